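# Angular quadrature on the gantry/couch sphere and multigroup energy grids.
#
# Ordinates are labelled by IEC61217-style couch and gantry angles.  The
# adopted Cartesian convention (documented, self-consistent; absolute
# orientation is not asserted anywhere):
#   mu  = sin(g) * cos(c)
#   eta = -sin(g) * sin(c)
#   xi  = cos(g)
# so that gantry 0 deg is the +z pole and gantry 180 deg the -z pole, with the
# couch angle degenerate at both poles.

#' Direction cosines from couch and gantry angles
#'
#' Maps IEC61217-style couch/gantry angles to a Cartesian unit vector under
#' the package's documented convention.  The mapping is degenerate at gantry
#' 0 and 180 degrees (poles), where any couch angle yields the same vector.
#'
#' @param couch_deg Couch angle in degrees, `[0, 360)`.
#' @param gantry_deg Gantry angle in degrees, `[0, 360)`.
#' @return Numeric vector `c(mu, eta, xi)` of unit length.
#' @examples
#' direction_from_angles(0, 0)    # +z pole
#' direction_from_angles(0, 90)   # lateral
#' @export
direction_from_angles <- function(couch_deg, gantry_deg) {
  c <- couch_deg * pi / 180
  g <- gantry_deg * pi / 180
  v <- c(sin(g) * cos(c), -sin(g) * sin(c), cos(g))
  # guard against rounding for cardinal angles
  v[abs(v) < 1e-15] <- 0
  v
}

#' Couch and gantry angles from a unit direction
#'
#' Inverse of [direction_from_angles()]; away from the poles the round trip
#' is exact to well below 1e-9 degrees.
#'
#' @param v Numeric unit vector `c(mu, eta, xi)`.
#' @return `c(couch_deg, gantry_deg)` with both angles in `[0, 360)`.
#' @export
angles_from_direction <- function(v) {
  g <- acos(max(-1, min(1, v[3]))) * 180 / pi
  c <- atan2(-v[2], v[1]) * 180 / pi
  c <- c %% 360
  if (abs(sin(g * pi / 180)) < 1e-12) c <- 0
  c(couch_deg = c, gantry_deg = g %% 360)
}

new_quadrature <- function(ordinates, kind, n_couch, n_gantry) {
  structure(list(ordinates = ordinates, kind = kind,
                 n_couch = n_couch, n_gantry = n_gantry),
            class = "angular_quadrature")
}

#' @export
print.angular_quadrature <- function(x, ...) {
  nz <- sum(x$ordinates$weight > 0)
  cat(sprintf("<angular_quadrature> kind=%s  C=%d G=%d  ordinates=%d (%d with weight > 0)\n",
              x$kind, x$n_couch, x$n_gantry, nrow(x$ordinates), nz))
  invisible(x)
}

#' Standard angular quadrature (4 couch x 8 gantry, pole-collapsed)
#'
#' Gantry angles are `{0, 47.5, 90, 132.5, 180, 227.5, 270, 312.5}` degrees
#' (approximately 45 degree spacing with the diagonals biased by 2.5 degrees
#' towards the lateral directions) and couch angles `{270, 315, 0, 45}`.
#' Ordinates at gantry 0 or 180 with non-zero couch angle duplicate the pole
#' direction and carry zero weight; all others carry `4*pi/(C*G)` steradians.
#' Exactly 26 distinct directions have non-zero weight.
#'
#' Note the non-zero weights sum to `26 * 4*pi/32 = 3.25*pi`, not `4*pi`; the
#' printed uniform weighting is kept literally and overall normalisation is
#' absorbed by the empirical cross-section factors (see the methods vignette).
#'
#' @return An `angular_quadrature` object whose `ordinates` data frame has
#'   columns `couch_deg`, `gantry_deg`, `mu`, `eta`, `xi`, `weight`.
#' @export
build_standard_angular_quadrature <- function() {
  gantry <- c(0, 47.5, 90, 132.5, 180, 227.5, 270, 312.5)
  couch <- c(270, 315, 0, 45)
  C <- length(couch); G <- length(gantry)
  grid <- expand.grid(couch_deg = couch, gantry_deg = gantry,
                      KEEP.OUT.ATTRS = FALSE)
  w0 <- 4 * pi / (C * G)
  pole <- grid$gantry_deg %in% c(0, 180)
  grid$weight <- ifelse(pole & grid$couch_deg != 0, 0, w0)
  dirs <- t(mapply(direction_from_angles, grid$couch_deg, grid$gantry_deg))
  grid$mu <- dirs[, 1]; grid$eta <- dirs[, 2]; grid$xi <- dirs[, 3]
  grid <- grid[, c("couch_deg", "gantry_deg", "mu", "eta", "xi", "weight")]
  new_quadrature(grid, "standard", C, G)
}

#' Fine angular quadrature (18 couch x 36 gantry, sine-weighted)
#'
#' Ordinates at 10 degree separation in both couch and gantry angle, with
#' solid-angle weights `w(c, g) = w0 * sin(g)` and
#' `w0 = 2 * pi^2 / (C * G)`, so that gantry-90-degree ordinates carry `w0`
#' and the polar ordinates (gantry 0 and 180) carry zero weight.
#'
#' @return An `angular_quadrature` object, `kind = "fine"`.
#' @export
build_fine_angular_quadrature <- function() {
  couch <- seq(0, 170, by = 10)
  gantry <- seq(0, 350, by = 10)
  C <- length(couch); G <- length(gantry)
  grid <- expand.grid(couch_deg = couch, gantry_deg = gantry,
                      KEEP.OUT.ATTRS = FALSE)
  w0 <- 2 * pi^2 / (C * G)
  grid$weight <- pmax(0, w0 * abs(sin(grid$gantry_deg * pi / 180)))
  # sin() of gantry: the printed formula; gantry beyond 180 mirrors the sphere
  grid$weight[grid$gantry_deg %in% c(0, 180)] <- 0
  dirs <- t(mapply(direction_from_angles, grid$couch_deg, grid$gantry_deg))
  grid$mu <- dirs[, 1]; grid$eta <- dirs[, 2]; grid$xi <- dirs[, 3]
  grid <- grid[, c("couch_deg", "gantry_deg", "mu", "eta", "xi", "weight")]
  new_quadrature(grid, "fine", C, G)
}

#' Multigroup energy grid
#'
#' Photon group energies rise in 0.5 MeV steps to 4.0 MeV and then in 1.0 MeV
#' steps to 10.0 MeV (14 groups); proton group energies rise in 5 MeV steps
#' from 5 to 250 MeV (50 groups).  Electrons reuse the photon grid (a
#' documented choice; pass `particle = "electron"`).  Group boundaries lie
#' midway between adjacent group energies and the within-group spectral
#' density is `f_E = 1 / (E_g_plus - E_g_minus)` so that the group integral
#' of the continuous fluence equals the group fluence exactly.
#'
#' @param particle One of `"photon"`, `"electron"`, `"proton"`.
#' @return An `energy_grid` object: data frame with columns `group`,
#'   `energy`, `lower`, `upper`, `f_E` plus attributes `particle`.
#' @export
build_energy_grid <- function(particle = c("photon", "electron", "proton")) {
  particle <- match.arg(particle)
  E <- switch(particle,
    photon = ,
    electron = c(seq(0.5, 4, by = 0.5), seq(5, 10, by = 1)),
    proton = seq(5, 250, by = 5))
  mid <- (E[-1] + E[-length(E)]) / 2
  lower <- c(E[1] - (mid[1] - E[1]), mid)
  upper <- c(mid, E[length(E)] + (E[length(E)] - mid[length(mid)]))
  g <- data.frame(group = seq_along(E), energy = E, lower = lower,
                  upper = upper, f_E = 1 / (upper - lower))
  structure(g, particle = particle, class = c("energy_grid", "data.frame"))
}

#' Locate the energy group containing an energy
#'
#' Energies below the lowest group boundary return `0` (local deposition /
#' cutoff handling); energies above the top boundary are clamped into the
#' highest group.
#'
#' @param E_MeV Numeric vector of energies in MeV.
#' @param grid An `energy_grid`.
#' @return Integer vector of group indices (0 = below cutoff).
#' @export
energy_group_of <- function(E_MeV, grid) {
  idx <- findInterval(E_MeV, c(grid$lower[1], grid$upper), left.open = FALSE)
  idx[E_MeV < grid$lower[1]] <- 0L
  pmin(idx, nrow(grid))
}

#' Bilinear assignment of a beam direction to quadrature ordinates
#'
#' Distributes a beam with the given couch/gantry angles over the four
#' encompassing ordinates of the quadrature in a process analogous to
#' bilinear interpolation.  The gantry and couch axes are treated as
#' periodic (wrap-around at 360 degrees).  The four fractions are in
#' `[0, 1]` and sum to one; a beam lying exactly on an ordinate receives
#' fraction one there.
#'
#' @param beam_couch,beam_gantry Beam angles in degrees.
#' @param quadrature An `angular_quadrature`.
#' @return Data frame with columns `ordinate` (row index into
#'   `quadrature$ordinates`) and `fraction`.
#' @export
assign_beam_to_ordinates <- function(beam_couch, beam_gantry, quadrature) {
  ords <- quadrature$ordinates
  gs <- sort(unique(ords$gantry_deg))
  cs <- sort(unique(ords$couch_deg))
  br_g <- .bracket_periodic(beam_gantry, gs)
  br_c <- .bracket_periodic(beam_couch, cs)
  # fractions per the bilinear formulae (gantry index first, couch second)
  f <- c(br_g$f1 * br_c$f1, br_g$f2 * br_c$f1,
         br_g$f1 * br_c$f2, br_g$f2 * br_c$f2)
  ang <- rbind(c(br_c$a1, br_g$a1), c(br_c$a1, br_g$a2),
               c(br_c$a2, br_g$a1), c(br_c$a2, br_g$a2))
  idx <- integer(4)
  pole_g <- c(0, 180)
  for (q in 1:4) {
    cq <- ang[q, 1]
    # at the poles the couch angle is degenerate: route to the couch-0 row,
    # which is the one the standard quadrature leaves with non-zero weight
    if (quadrature$kind == "standard" && ang[q, 2] %in% pole_g) cq <- 0
    hit <- which(ords$couch_deg == cq & ords$gantry_deg == ang[q, 2])
    if (length(hit) == 0) {
      hit <- which(ords$couch_deg == 0 & ords$gantry_deg == ang[q, 2])
    }
    idx[q] <- hit[1]
  }
  # collapse duplicates (pole ordinates, exact hits)
  agg <- tapply(f, idx, sum)
  data.frame(ordinate = as.integer(names(agg)), fraction = as.numeric(agg),
             row.names = NULL)
}

# bracket an angle on a periodic sorted grid; returns the two grid angles and
# the bilinear fractions (f1 towards a1, f2 towards a2)
.bracket_periodic <- function(a, grid_angles) {
  a <- a %% 360
  exact <- which(abs(((grid_angles - a + 180) %% 360) - 180) < 1e-9)
  if (length(exact)) {
    g0 <- grid_angles[exact[1]]
    return(list(a1 = g0, a2 = g0, f1 = 1, f2 = 0))
  }
  below <- ((a - grid_angles) %% 360)
  i1 <- which.min(ifelse(below == 0, 360, below))   # nearest grid angle below
  above <- ((grid_angles - a) %% 360)
  i2 <- which.min(ifelse(above == 0, 360, above))   # nearest above
  a1 <- grid_angles[i1]; a2 <- grid_angles[i2]
  span <- (a2 - a1) %% 360
  d1 <- (a - a1) %% 360
  list(a1 = a1, a2 = a2, f1 = 1 - d1 / span, f2 = d1 / span)
}

#' Serialise a quadrature or energy grid to JSON
#'
#' Angles are written in degrees, energies in MeV and weights in steradians.
#'
#' @param x An `angular_quadrature` or `energy_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_quadrature_json <- function(x, path) {
  if (inherits(x, "angular_quadrature")) {
    out <- list(kind = x$kind, n_couch = x$n_couch, n_gantry = x$n_gantry,
                ordinates = x$ordinates)
  } else if (inherits(x, "energy_grid")) {
    out <- list(particle = attr(x, "particle"), groups = as.data.frame(x))
  } else stop("unsupported object")
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read back a quadrature written by [write_quadrature_json()]
#' @param path JSON file path.
#' @return An `angular_quadrature` or `energy_grid`.
#' @export
read_quadrature_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$ordinates)) {
    new_quadrature(as.data.frame(x$ordinates), x$kind, x$n_couch, x$n_gantry)
  } else {
    structure(as.data.frame(x$groups), particle = x$particle,
              class = c("energy_grid", "data.frame"))
  }
}

# distinct nonzero-weight directions, used by solvers (pole duplicates and
# zero-weight rows dropped); returns ordinate table with original row index
active_ordinates <- function(quadrature) {
  o <- quadrature$ordinates
  keep <- o$weight > 0
  o <- o[keep, , drop = FALSE]
  o$index <- which(keep)
  o
}
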