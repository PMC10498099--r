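# Fixed (unscattered) fluence sources: photon head-model fluence along
# divergent rays, proton CSDA energy maps and layer fluence, distribution
# over quadrature ordinates and uncertainty-kernel offsets.

# radiological depth (mm, water-equivalent) from the grid entry point to
# every voxel centre, along rays from the source position
radiological_depths <- function(phantom, src) {
  pts <- voxel_centres(phantom)
  cpp_radiological_depth(as.numeric(phantom$rho), phantom$dims,
                         phantom$spacing, src, pts,
                         min(phantom$spacing) / 4)
}

# per-voxel beam geometry: distance from source, depth along the beam axis,
# beam's-eye-view coordinates scaled to the isocentre plane, off-axis radius
beam_frame <- function(beam, phantom) {
  geo <- beam_geometry(beam, phantom)
  pts <- voxel_centres(phantom)
  rel <- sweep(pts, 2, geo$src)
  along <- as.numeric(rel %*% geo$dir)
  bx <- as.numeric(rel %*% geo$ex) * beam$sad_mm / along
  by <- as.numeric(rel %*% geo$ey) * beam$sad_mm / along
  list(geo = geo, along = along, bev_x = bx, bev_y = by,
       dist = sqrt(rowSums(rel^2)),
       zrad = radiological_depths(phantom, geo$src))
}

# aperture convolved with the Gaussian source: separable error-function
# transmission for a rectangular field, evaluated in isocentre-plane
# coordinates; sigma_eff is the source width projected to the iso plane
.fluence_profile <- function(bx, by, field_mm, sigma_mm, along, sad_mm) {
  T <- rep(1, length(bx))
  for (axis in 1:2) {
    x <- if (axis == 1) bx else by
    half <- field_mm[axis] / 2
    sig <- pmax(sigma_mm[axis] * abs(along - sad_mm) / sad_mm, 1e-6)
    T <- T * 0.5 * (erf((half - x) / (sqrt(2) * sig)) +
                    erf((half + x) / (sqrt(2) * sig)))
  }
  T
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Unscattered photon fluence from the dual-source head model
#'
#' For each energy group, the fluence at a voxel is the inverse-square
#' factor times the aperture-convolved source transmission, the tabulated
#' profile (flat by default), the spectrum weight, and exponential
#' attenuation over the radiological depth with optional off-axis softening:
#' `(sad/d)^2 * (omega (x) s) * psi * eta(E) * exp(-mu0 z_rad - mu' r z_rad)`.
#'
#' @param beam A photon `beam_config`.
#' @param phantom A `voxel_phantom`.
#' @param energy_grid Photon `energy_grid`.
#' @param mu0 Attenuation function from [load_attenuation_table()].
#' @param secondary_fraction Weight of the broad secondary source (default
#'   0.05; widths 18 mm at 150 mm from the primary).
#' @return V x G matrix of unscattered fluence (V voxels, column-major).
#' @export
photon_unscattered_fluence <- function(beam, phantom,
                                       energy_grid = build_energy_grid("photon"),
                                       mu0 = load_attenuation_table(),
                                       secondary_fraction = 0.05) {
  bf <- beam_frame(beam, phantom)
  inside <- bf$along > 0
  if (!any(inside)) {
    warning("beam misses the phantom; zero fluence")
    return(matrix(0, nrow(voxel_centres(phantom)), nrow(energy_grid)))
  }
  invsq <- ifelse(inside, (beam$sad_mm / bf$dist)^2, 0)
  Tpri <- .fluence_profile(bf$bev_x, bf$bev_y, beam$field_mm,
                           beam$source_sigma_mm, bf$along, beam$sad_mm)
  # secondary source: broad Gaussian 150 mm downstream of the primary
  sec_sigma <- c(18, 18) * beam$sad_mm / (beam$sad_mm - 150)
  Tsec <- .fluence_profile(bf$bev_x, bf$bev_y, beam$field_mm, sec_sigma,
                           bf$along, beam$sad_mm)
  Ttot <- (1 - secondary_fraction) * Tpri + secondary_fraction * Tsec
  roff <- sqrt(bf$bev_x^2 + bf$bev_y^2)
  spec <- merge(energy_grid, beam$spectrum,
                by.x = "energy", by.y = "energy_MeV", all.x = TRUE)
  spec$weight[is.na(spec$weight)] <- 0
  spec <- spec[order(spec$group), ]
  w <- spec$weight / sum(spec$weight)
  out <- matrix(0, length(invsq), nrow(energy_grid))
  base <- invsq * Ttot
  for (g in seq_len(nrow(energy_grid))) {
    if (w[g] <= 0) next
    att <- exp(-(mu0(energy_grid$energy[g]) +
                 beam$mu_prime * roff) * bf$zrad)
    out[, g] <- base * w[g] * att
  }
  out
}

#' Residual proton energy along a ray (CSDA recursion)
#'
#' `e(r_{n+1}) = e(r_n) - |r_{n+1} - r_n| rho(r_n) S(e(r_n))`, clamped at
#' zero, with the mass collision stopping power of water-scaled media.
#'
#' @param path_mm Cumulative geometric path positions along the ray (mm).
#' @param rho Mass density (g/cm^3) in each path interval (length
#'   `length(path_mm) - 1`, or scalar).
#' @param E0_MeV Initial energy, MeV.
#' @return Residual energy at each path position (starts at `E0_MeV`).
#' @export
csda_energy_map <- function(path_mm, rho, E0_MeV) {
  n <- length(path_mm)
  if (length(rho) == 1) rho <- rep(rho, n - 1)
  e <- numeric(n)
  e[1] <- E0_MeV
  for (i in seq_len(n - 1)) {
    if (e[i] <= 0) { e[i + 1] <- 0; next }
    S <- proton_stopping_power(max(e[i], 1)) / 10   # MeV/mm at rho = 1
    e[i + 1] <- max(e[i] - (path_mm[i + 1] - path_mm[i]) * rho[i] * S, 0)
  }
  e
}

# Residual-energy lookup table on a fine radiological-depth axis: since the
# medium is water-scaled, the residual energy is a function of radiological
# depth only.  Midpoint (second-order) steps remove the first-order bias the
# plain recursion carries at voxel-sized steps (csda_energy_map() is the
# voxel-level recursion).  The depth axis is then anchored so the
# zero-energy depth equals the nominal range csda_range(E0): each layer is
# commissioned to its nominal range, as beam data would be, which keeps the
# transport engine and the analytic comparator on a shared range-energy
# calibration (the Bethe stopping-power shape still governs the profile
# within the range; the anchoring rescales depths by < 1.5%).
.csda_depth_table <- function(E0_MeV, step_mm = 0.25, max_mm = NULL) {
  if (is.null(max_mm)) max_mm <- csda_range(E0_MeV) * 1.15 + 10
  r <- seq(0, max_mm, by = step_mm)
  e <- numeric(length(r))
  e[1] <- E0_MeV
  for (i in seq_len(length(r) - 1)) {
    if (e[i] <= 0) { e[i + 1] <- 0; next }
    S1 <- proton_stopping_power(max(e[i], 1)) / 10
    ehalf <- max(e[i] - step_mm / 2 * S1, 0)
    S2 <- if (ehalf > 0) proton_stopping_power(max(ehalf, 1)) / 10 else S1
    e[i + 1] <- max(e[i] - step_mm * S2, 0)
  }
  scale <- 1
  if (any(e <= 0)) {
    r_end <- r[which(e <= 0)[1]]
    scale <- csda_range(E0_MeV) / r_end
    r <- r * scale
  }
  # `scale` rescales depths to the nominal range, i.e. the effective
  # stopping power is S/scale; energy conservation requires the scored
  # fluence to carry the reciprocal factor (see proton_unscattered_fluence)
  list(r = r, e = e, scale = scale)
}

#' Unscattered proton fluence for a layered (SOBP) beam
#'
#' For each energy layer, the residual energy at every voxel follows the
#' CSDA recursion on the radiological depth axis; the voxel's fluence is the
#' inverse-square factor times the profile-convolved source, the layer
#' weight, and the loss factor `1 - lambda z_rad - tau sigma_Mott_tot`
#' (floored at zero), assigned to the energy group containing the local
#' residual energy.
#'
#' @param beam A proton `beam_config` with `$layers`.
#' @param phantom A `voxel_phantom`.
#' @param energy_grid Proton `energy_grid`.
#' @param xs Proton tables from [build_proton_xs_tables()] (for the elastic
#'   loss term); `NULL` drops the `tau` term.
#' @return V x G matrix of unscattered fluence by group.
#'
#' @details Near the end of range the residual energy sweeps through several
#' groups within a single voxel, so a voxel's fluence is split over groups
#' in proportion to the radiological path length the protons spend in each
#' group inside the voxel (exact interval overlap on the CSDA depth-energy
#' table).  Point sampling at voxel centres would alias against the
#' layer-range comb; the path-fraction split is exact and grid-independent.
#' @export
proton_unscattered_fluence <- function(beam, phantom,
                                       energy_grid = build_energy_grid("proton"),
                                       xs = NULL) {
  stopifnot(!is.null(beam$layers))
  bf <- beam_frame(beam, phantom)
  inside <- bf$along > 0
  invsq <- ifelse(inside, (beam$sad_mm / bf$dist)^2, 0)
  Tpsi <- .fluence_profile(bf$bev_x, bf$bev_y, beam$field_mm,
                           beam$source_sigma_mm, bf$along, beam$sad_mm)
  base <- invsq * Tpsi
  rho_c_rel <- as.numeric(phantom$rho_c_rel)
  # radiological half-thickness of a voxel along the dominant beam axis
  ax <- which.max(abs(bf$geo$dir))
  half <- as.numeric(phantom$rho) * phantom$spacing[ax] / 2
  za <- pmax(bf$zrad - half, 0)
  zb <- bf$zrad + half
  width <- pmax(zb - za, 1e-9)
  G <- nrow(energy_grid)
  out <- matrix(0, length(base), G)
  act <- which(base > 0)
  for (l in seq_len(nrow(beam$layers))) {
    E0 <- beam$layers$energy_MeV[l]
    tab <- .csda_depth_table(E0)
    eta <- beam$layers$weight[l] / tab$scale   # energy-conserving anchoring
    # strictly decreasing branch of e(r) plus the range endpoint, inverted
    pos <- tab$e > 0
    iend <- if (all(pos)) length(tab$e) else which(!pos)[1]
    eb <- rev(c(tab$e[seq_len(iend - 1)], 0))
    rb <- rev(tab$r[seq_len(iend)])
    depth_at <- function(E) {
      stats::approx(eb, rb, xout = pmin(E, E0), rule = 2)$y
    }
    gmax <- energy_group_of(E0, energy_grid)
    if (gmax < 1) next
    for (g in seq_len(gmax)) {
      lo_d <- depth_at(energy_grid$upper[g])   # enters group g here
      hi_d <- depth_at(energy_grid$lower[g])   # leaves group g here
      if (hi_d <= 0) next
      frac <- pmax(0, pmin(zb[act], hi_d) - pmax(za[act], lo_d)) / width[act]
      sel <- frac > 0
      if (!any(sel)) next
      v <- act[sel]
      loss <- 1 - beam$lambda * bf$zrad[v]
      if (!is.null(xs)) {
        loss <- loss - beam$tau * rho_c_rel[v] * xs$mott_tot[g]
      }
      out[v, g] <- out[v, g] + eta * base[v] * frac[sel] * pmax(loss, 0)
    }
    # protons falling below the lowest group boundary deposit the remaining
    # energy locally: represented as equivalent group-1 fluence spread over
    # the residual sub-cutoff path (energy-conserving cutoff handling)
    E_cut <- energy_grid$lower[1]
    d_cut <- depth_at(E_cut)
    r_end <- max(rb)
    if (r_end > d_cut) {
      S1 <- proton_stopping_power(energy_grid$energy[1]) / 10  # MeV/mm
      ov <- pmax(0, pmin(zb[act], r_end) - pmax(za[act], d_cut)) /
        (r_end - d_cut)
      sel <- ov > 0
      if (any(sel)) {
        v <- act[sel]
        loss <- pmax(1 - beam$lambda * bf$zrad[v] -
                     (if (is.null(xs)) 0 else
                        beam$tau * rho_c_rel[v] * xs$mott_tot[1]), 0)
        out[v, 1] <- out[v, 1] +
          eta * base[v] * loss * ov[sel] * (E_cut / S1) / width[v]
      }
    }
  }
  out
}

#' Build the spatial-uncertainty kernel
#'
#' Outer product of three axis distributions defined on offsets from -16 to
#' +16 mm in 2 mm steps (17 points each, 4913 combinations), resampled to
#' the 64 highest-probability points with probabilities rescaled to sum to
#' one (conservation of energy).  Ties are broken by lexicographic offset
#' order, so the construction is deterministic.
#'
#' @param p_x,p_y,p_z Numeric vectors of length 17 (non-negative; each is
#'   normalised internally).  Defaults give the identity kernel (delta at
#'   zero offset).
#' @param n_keep Number of points kept (default 64).
#' @return An `uncertainty_kernel`: data frame `x_mm`, `y_mm`, `z_mm`, `p`
#'   with attribute `n_raw = 4913`.
#' @export
build_uncertainty_kernel <- function(p_x = NULL, p_y = NULL, p_z = NULL,
                                     n_keep = 64) {
  off <- seq(-16, 16, by = 2)
  delta <- function() { v <- numeric(17); v[9] <- 1; v }
  if (is.null(p_x)) p_x <- delta()
  if (is.null(p_y)) p_y <- delta()
  if (is.null(p_z)) p_z <- delta()
  for (p in list(p_x, p_y, p_z)) {
    if (length(p) != 17 || any(p < 0) || sum(p) <= 0) {
      stop("each axis distribution must be 17 non-negative values with positive sum")
    }
  }
  p_x <- p_x / sum(p_x); p_y <- p_y / sum(p_y); p_z <- p_z / sum(p_z)
  full <- expand.grid(x_mm = off, y_mm = off, z_mm = off,
                      KEEP.OUT.ATTRS = FALSE)
  full$p <- as.numeric(outer(outer(p_x, p_y), p_z))
  ord <- order(-full$p, full$x_mm, full$y_mm, full$z_mm)
  keep <- head(ord[full$p[ord] > 0], n_keep)
  kern <- full[keep, , drop = FALSE]
  kern$p <- kern$p / sum(kern$p)
  rownames(kern) <- NULL
  structure(kern, n_raw = nrow(full), class = c("uncertainty_kernel",
                                                "data.frame"))
}

#' Write an uncertainty kernel to CSV (offset mm, probability)
#' @param kernel From [build_uncertainty_kernel()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(kernel, path) {
  utils::write.csv(as.data.frame(kernel), path, row.names = FALSE)
  invisible(path)
}

#' Read an uncertainty kernel from CSV
#' @param path CSV path written by [write_kernel_csv()].
#' @return An `uncertainty_kernel`.
#' @export
read_kernel_csv <- function(path) {
  k <- utils::read.csv(path)
  structure(k, class = c("uncertainty_kernel", "data.frame"))
}

#' Distribute per-voxel fluence over ordinates and kernel offsets
#'
#' Splits a V x G unscattered-fluence matrix over the four quadrature
#' ordinates encompassing the beam direction (bilinear fractions) and over
#' the offsets of the spatial-uncertainty kernel (voxel shifts rounded to
#' the grid).  Fluence shifted outside the grid is dropped; everything else
#' is conserved.
#'
#' @param fluence V x G matrix from [photon_unscattered_fluence()] or
#'   [proton_unscattered_fluence()].
#' @param beam A `beam_config`.
#' @param quadrature An `angular_quadrature`.
#' @param phantom The `voxel_phantom` (for grid dimensions).
#' @param kernel An `uncertainty_kernel`, or `NULL` for the identity.
#' @return A `fluence_tensor`: list of per-group `N x V` matrices
#'   (`N` = active ordinates), with attributes `quadrature`, `component`.
#' @export
distribute_unscattered <- function(fluence, beam, quadrature, phantom,
                                   kernel = NULL) {
  ords <- active_ordinates(quadrature)
  asg <- assign_beam_to_ordinates(beam$couch_deg, beam$gantry_deg, quadrature)
  # map original ordinate rows to active (nonzero-weight) rows
  act <- match(asg$ordinate, ords$index)
  if (anyNA(act)) {
    drop <- is.na(act)
    if (sum(asg$fraction[drop]) > 1e-9) {
      warning("part of the beam falls on zero-weight ordinates; dropped")
    }
    asg <- asg[!drop, , drop = FALSE]; act <- act[!drop]
  }
  V <- nrow(fluence); G <- ncol(fluence); N <- nrow(ords)
  if (is.null(kernel)) {
    kernel <- data.frame(x_mm = 0, y_mm = 0, z_mm = 0, p = 1)
  }
  d <- phantom$dims
  shifted <- .apply_kernel_vg(fluence, phantom, kernel)
  tensor <- vector("list", G)
  for (g in seq_len(G)) {
    m <- matrix(0, N, V)
    col <- shifted[, g]
    if (any(col != 0)) {
      for (q in seq_len(nrow(asg))) {
        m[act[q], ] <- m[act[q], ] + asg$fraction[q] * col
      }
    }
    tensor[[g]] <- m
  }
  structure(tensor, component = "unscattered", dims = d,
            class = "fluence_tensor")
}

# distribute a V x G fluence matrix over the kernel offsets (voxel shifts
# rounded to the grid); mass shifted outside the grid is dropped
.apply_kernel_vg <- function(fluence, phantom, kernel) {
  shifted <- matrix(0, nrow(fluence), ncol(fluence))
  for (q in seq_len(nrow(kernel))) {
    sh <- round(c(kernel$x_mm[q], kernel$y_mm[q], kernel$z_mm[q]) /
                phantom$spacing)
    shifted <- shifted + kernel$p[q] * .shift_grid(fluence, phantom$dims, sh)
  }
  shifted
}

# shift a V x G matrix (column-major voxel order) by integer voxel offsets,
# zero-filling; the fluence at (x + sx) receives the value from x
.shift_grid <- function(m, dims, shift) {
  if (all(shift == 0)) return(m)
  out <- array(0, c(dims, ncol(m)))
  src <- array(m, c(dims, ncol(m)))
  i1 <- pmax(1, 1 + shift[1]):pmin(dims[1], dims[1] + shift[1])
  j1 <- pmax(1, 1 + shift[2]):pmin(dims[2], dims[2] + shift[2])
  k1 <- pmax(1, 1 + shift[3]):pmin(dims[3], dims[3] + shift[3])
  if (length(i1) < 1 || length(j1) < 1 || length(k1) < 1) {
    return(matrix(0, nrow(m), ncol(m)))
  }
  out[i1, j1, k1, ] <- src[i1 - shift[1], j1 - shift[2], k1 - shift[3], ,
                           drop = FALSE]
  matrix(out, nrow(m), ncol(m))
}
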