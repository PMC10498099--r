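# Absorbed dose from charged-particle fluence, normalisation and curve
# extraction.

#' Absorbed dose from a charged-particle fluence tensor
#'
#' `D = (1/rho) * sum_g S(E_g) * sum_n Phi[n, g]` with the mass collision
#' stopping power at the group energies.  Vacuum voxels (`rho = 0`) report
#' zero dose and are flagged in the `vacuum` attribute.
#'
#' @param fluence Fluence tensor (list over groups of N x V matrices) for
#'   electrons or protons.
#' @param energy_grid Matching `energy_grid`.
#' @param phantom The `voxel_phantom`.
#' @param particle `"electron"` or `"proton"` (selects the stopping power).
#' @return A `dose_grid`: list with `dose` (array, relative units), `dims`,
#'   `spacing`, attribute-like fields `vacuum` (logical array) and
#'   `normalisation` (NA until [normalize_pair()]).
#' @export
dose_from_fluence <- function(fluence, energy_grid, phantom,
                              particle = c("electron", "proton")) {
  particle <- match.arg(particle)
  S <- switch(particle,
              electron = electron_stopping_power(energy_grid$energy),
              proton = proton_stopping_power(energy_grid$energy))
  V <- prod(phantom$dims)
  phi <- tensor_scalar(fluence, V)
  rho <- as.numeric(phantom$rho)
  vac <- rho <= 0
  d <- as.numeric(phi %*% S[seq_len(ncol(phi))])
  d[!vac] <- d[!vac] / rho[!vac]
  d[vac] <- 0
  structure(list(dose = array(d, phantom$dims), dims = phantom$dims,
                 spacing = phantom$spacing,
                 vacuum = array(vac, phantom$dims),
                 normalisation = NA_real_),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d, max = %g%s\n",
              x$dims[1], x$dims[2], x$dims[3], max(x$dose),
              if (is.na(x$normalisation)) " (unnormalised)" else "%"))
  invisible(x)
}

#' Normalise an LBTE dose grid and scale a comparator by the same factor
#'
#' The three-dimensional maximum of the LBTE dose is designated 100%; the
#' comparator (convolution or analytic curve/grid) is multiplied by the
#' identical factor so the relative magnitude of the two methods is
#' preserved.
#'
#' @param lbte_dose A `dose_grid` (or numeric array/vector).
#' @param comparator_dose Numeric array/vector or `dose_grid` on any grid.
#' @return List `lbte`, `comparator` (same classes as supplied, values in
#'   percent) and `factor`.
#' @export
normalize_pair <- function(lbte_dose, comparator_dose) {
  dl <- if (inherits(lbte_dose, "dose_grid")) lbte_dose$dose else lbte_dose
  m <- max(dl)
  if (!is.finite(m) || m <= 0) stop("LBTE dose maximum is not positive")
  f <- 100 / m
  scale_obj <- function(x) {
    if (inherits(x, "dose_grid")) {
      x$dose <- x$dose * f; x$normalisation <- f; x
    } else x * f
  }
  list(lbte = scale_obj(lbte_dose), comparator = scale_obj(comparator_dose),
       factor = f)
}

#' Extract central-axis depth dose and a lateral profile
#'
#' Samples the dose along the beam axis (nearest voxel line) and across it
#' at the stated isocentric depth (default 150 mm).  Only axis-aligned
#' beams are supported (the benchmarks use gantry 0).
#'
#' @param dose A `dose_grid`.
#' @param beam The `beam_config` (for geometry).
#' @param phantom The `voxel_phantom`.
#' @param profile_depth_mm Depth of the lateral profile (default 150).
#' @return List of data frames: `depth` (`depth_mm`, `dose`), `profile`
#'   (`offset_mm`, `dose`).
#' @export
extract_curves <- function(dose, beam, phantom, profile_depth_mm = 150) {
  geo <- beam_geometry(beam, phantom)
  ax <- which.max(abs(geo$dir))
  if (max(abs(geo$dir)) < 0.999) {
    stop("extract_curves supports axis-aligned beams only")
  }
  d <- phantom$dims; s <- phantom$spacing
  ctr <- pmin(pmax(round(geo$iso / s + 0.5), 1), d)
  # depth index runs along the beam axis in the travel direction
  ij <- ctr
  depth_idx <- if (geo$dir[ax] > 0) seq_len(d[ax]) else rev(seq_len(d[ax]))
  depth_mm <- (seq_len(d[ax]) - 0.5) * s[ax]
  pick <- function(i_ax, i_lat = NULL, lat_axis = NULL) {
    ii <- ij
    ii[ax] <- i_ax
    if (!is.null(i_lat)) ii[lat_axis] <- i_lat
    dose$dose[ii[1], ii[2], ii[3]]
  }
  dd <- vapply(depth_idx, pick, numeric(1))
  lat_axis <- setdiff(1:3, ax)[1]
  k_depth <- depth_idx[which.min(abs(depth_mm - profile_depth_mm))]
  prof <- vapply(seq_len(d[lat_axis]), function(il) {
    pick(k_depth, il, lat_axis)
  }, numeric(1))
  off <- ((seq_len(d[lat_axis]) - 0.5) * s[lat_axis]) - geo$iso[lat_axis]
  list(depth = data.frame(depth_mm = depth_mm, dose = dd),
       profile = data.frame(offset_mm = off, dose = prof))
}

#' Percent-of-local-dose difference between two curves
#'
#' `100 * (a - b) / ref` with `ref` the local reference dose (`b` by
#' default).  Points where the reference is below `exclude_below` percent of
#' its maximum are reported as `NA` and excluded from any maximum-difference
#' statistic, mirroring how low-dose extremes are excluded from published
#' difference scales.
#'
#' @param a,b Numeric dose vectors on a common axis.
#' @param exclude_below Exclusion threshold as a fraction of the reference
#'   maximum (default 0.05).
#' @return Numeric vector of percent differences (NA where excluded).
#' @export
percent_local_difference <- function(a, b, exclude_below = 0.05) {
  ref <- b
  out <- 100 * (a - b) / ref
  out[ref < exclude_below * max(ref)] <- NA_real_
  out
}
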