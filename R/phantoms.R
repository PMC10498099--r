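# Synthetic voxel phantoms and benchmark beam configurations.
#
# Grid convention: column-major arrays dim c(I, J, K); world coordinates in
# mm with the origin at the corner of voxel (1,1,1); voxel centres at
# ((i-1/2) dx, (j-1/2) dy, (k-1/2) dz).  Synthetic phantoms are
# water-equivalent scaled: relative electron and core densities equal the
# relative mass density.

#' Construct a voxel phantom
#'
#' @param dims_mm Outer dimensions `c(x, y, z)` in mm.
#' @param voxel_mm Isotropic voxel size in mm (or length-3 vector).
#' @param density Base mass density, g/cm^3.
#' @param block Optional inhomogeneity: a list with `dims_mm`, `corner_mm`
#'   (position of its lower corner) and `density`.
#' @return A `voxel_phantom`: list with `dims`, `spacing`, `rho`,
#'   `rho_e_rel`, `rho_c_rel` (arrays), `extent_mm`.
#' @export
make_phantom <- function(dims_mm, voxel_mm, density = 1.0, block = NULL) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (any(dims_mm <= 0) || any(voxel_mm <= 0)) stop("invalid dimensions")
  dims <- as.integer(round(dims_mm / voxel_mm))
  rho <- array(density, dims)
  if (!is.null(block)) {
    lo <- block$corner_mm; hi <- block$corner_mm + block$dims_mm
    if (any(lo < 0) || any(hi > dims * voxel_mm)) {
      stop("inhomogeneity block outside phantom")
    }
    i <- pmax(1, floor(lo / voxel_mm) + 1)
    j <- pmin(dims, ceiling(hi / voxel_mm))
    rho[i[1]:j[1], i[2]:j[2], i[3]:j[3]] <- block$density
  }
  structure(list(dims = dims, spacing = voxel_mm, rho = rho,
                 rho_e_rel = rho, rho_c_rel = rho,
                 extent_mm = dims * voxel_mm),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels @ %g/%g/%g mm, rho in [%g, %g] g/cm^3\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              min(x$rho), max(x$rho)))
  invisible(x)
}

#' Named phantom presets
#'
#' `water` (1.0), `lung` (0.25) and `bone` (1.3 g/cm^3) are the homogeneous
#' convergence-study materials; `inhomogeneity` places a
#' 100 x 100 x 300 mm block of the given density (one of 0, 0.23, 1.51,
#' 4.50 g/cm^3 in the validation set) into a 300 mm cube of water.
#'
#' @param name Preset name.
#' @param voxel_mm Voxel size, mm.
#' @param dims_mm Outer dimensions (default 300 mm cube).
#' @param block_density Density of the inhomogeneity block (preset
#'   `inhomogeneity` only).
#' @return A `voxel_phantom`.
#' @export
phantom_preset <- function(name = c("water", "lung", "bone", "inhomogeneity"),
                           voxel_mm = 2.5, dims_mm = c(300, 300, 300),
                           block_density = 0.23) {
  name <- match.arg(name)
  dens <- c(water = 1.0, lung = 0.25, bone = 1.3)
  if (name == "inhomogeneity") {
    ctr <- (dims_mm - c(100, 100, 300)) / 2
    ctr[3] <- 0
    make_phantom(dims_mm, voxel_mm, 1.0,
                 block = list(dims_mm = c(100, 100, 300), corner_mm = ctr,
                              density = block_density))
  } else {
    make_phantom(dims_mm, voxel_mm, dens[[name]])
  }
}

#' Beam configuration
#'
#' Geometry follows the quadrature's angle convention: the beam travels
#' along `direction_from_angles(couch, gantry)`; the source sits at the
#' isocentre minus SAD times that direction.  The isocentre defaults to the
#' centre of the phantom's x-y extent at depth `sad - ssd` below the
#' entrance face (a gantry-0 beam enters through the z = 0 face).
#'
#' @param particle `"photon"` or `"proton"`.
#' @param gantry_deg,couch_deg Beam angles, degrees.
#' @param sad_mm Source-axis distance (photon default 1000, proton 2300).
#' @param ssd_mm Source-surface distance.
#' @param field_mm Field size `c(x, y)` at the isocentre plane, mm.
#' @param source_sigma_mm Gaussian source width/length std dev, mm
#'   (photon primary default 0.8/1.0; proton 30/30).
#' @param iso_mm Isocentre in phantom coordinates (optional).
#' @param spectrum Photon spectrum data frame (`energy_MeV`, `weight`);
#'   default the shipped 6 MV table.
#' @param layers Proton energy layers (`energy_MeV`, `weight`); built with
#'   [sobp_layer_weights()] if omitted.
#' @param mu_prime Off-axis softening coefficient (default 0 for synthetic
#'   beams).
#' @param lambda Proton nuclear fluence loss per mm radiological path
#'   (default 5e-4).
#' @param tau Proton elastic fluence-loss coefficient (default 1e-3).
#' @return A `beam_config` list.
#' @export
beam_config <- function(particle = c("photon", "proton"),
                        gantry_deg = 0, couch_deg = 0,
                        sad_mm = if (particle == "proton") 2300 else 1000,
                        ssd_mm = sad_mm - 150,
                        field_mm = c(100, 100),
                        source_sigma_mm = if (particle == "proton")
                          c(30, 30) else c(0.8, 1.0),
                        iso_mm = NULL, spectrum = NULL, layers = NULL,
                        mu_prime = 0, lambda = 5e-4, tau = 1e-3) {
  particle <- match.arg(particle)
  if (particle == "photon" && is.null(spectrum)) {
    path <- system.file("extdata", "spectrum_6mv.csv", package = "ordose")
    spectrum <- utils::read.csv(path)
  }
  structure(list(particle = particle, gantry_deg = gantry_deg,
                 couch_deg = couch_deg, sad_mm = sad_mm, ssd_mm = ssd_mm,
                 field_mm = field_mm, source_sigma_mm = source_sigma_mm,
                 iso_mm = iso_mm, spectrum = spectrum, layers = layers,
                 mu_prime = mu_prime, lambda = lambda, tau = tau),
            class = "beam_config")
}

# resolve beam geometry against a phantom: direction, source position,
# isocentre, orthonormal beam's-eye-view axes
beam_geometry <- function(beam, phantom) {
  dir <- direction_from_angles(beam$couch_deg, beam$gantry_deg)
  iso <- beam$iso_mm
  if (is.null(iso)) {
    ext <- phantom$extent_mm
    # put the isocentre at depth sad - ssd below the entrance face along the
    # dominant beam axis, centred on the other two axes
    depth_iso <- beam$sad_mm - beam$ssd_mm
    iso <- c(ext[1] / 2, ext[2] / 2, ext[3] / 2)
    ax <- which.max(abs(dir))
    iso[ax] <- if (dir[ax] > 0) depth_iso else ext[ax] - depth_iso
  }
  src <- iso - beam$sad_mm * dir
  # BEV axes: ex orthogonal to dir (prefer world x), ey = dir x ex
  ref <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ex <- ref - sum(ref * dir) * dir
  ex <- ex / sqrt(sum(ex^2))
  ey <- c(dir[2] * ex[3] - dir[3] * ex[2],
          dir[3] * ex[1] - dir[1] * ex[3],
          dir[1] * ex[2] - dir[2] * ex[1])
  list(dir = dir, src = src, iso = iso, ex = ex, ey = ey)
}

#' Standard benchmark beam + phantom configurations
#'
#' The named validation setups: `photon_water` (100 x 100 mm field,
#' SAD 1000, SSD 850 on a 300 mm water cube), `proton_water` (100 x 100 mm,
#' SAD 2300, SSD 2150, SOBP layers spanning 115-174 MeV for a 100-200 mm
#' spread-out Bragg peak), and `*_desk` scaled-down variants on a 5 mm (or
#' coarser) grid small enough for continuous-integration runs.
#'
#' @param n_layers Number of proton energy layers for the SOBP (the passive
#'   beams divide the spectrum into many layers; default 100).
#' @return Named list of lists, each with `phantom` and `beam`.
#' @export
standard_benchmarks <- function(n_layers = 100) {
  lay <- sobp_layer_weights(100, 200, n_layers)
  list(
    photon_water = list(
      phantom = phantom_preset("water", voxel_mm = 2.5),
      beam = beam_config("photon", sad_mm = 1000, ssd_mm = 850)),
    proton_water = list(
      phantom = phantom_preset("water", voxel_mm = 2.5),
      beam = beam_config("proton", sad_mm = 2300, ssd_mm = 2150,
                         layers = lay)),
    photon_water_desk = list(
      phantom = make_phantom(c(200, 200, 300), 10),
      beam = beam_config("photon", sad_mm = 1000, ssd_mm = 850)),
    proton_water_desk = list(
      phantom = make_phantom(c(200, 200, 300), 5),
      beam = beam_config("proton", sad_mm = 2300, ssd_mm = 2150,
                         layers = lay))
  )
}

# voxel-centre coordinates (V x 3 matrix, column-major voxel order)
voxel_centres <- function(phantom) {
  d <- phantom$dims; s <- phantom$spacing
  xs <- (seq_len(d[1]) - 0.5) * s[1]
  ys <- (seq_len(d[2]) - 0.5) * s[2]
  zs <- (seq_len(d[3]) - 0.5) * s[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}
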