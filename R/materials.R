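# Material model: HU -> density / composition conversion, electron and proton
# mass collision stopping powers (water medium, Sternheimer density effect),
# range-energy relation and photon attenuation table.
#
# Unit conventions (documented also in the methods vignette):
#   rho    g/cm^3                 mass density
#   rho_e  electrons/mm^3         absolute electron density
#   rho_c  nuclei/mm^3            absolute atomic-core density
#   S      MeV cm^2 / g           mass collision stopping power
#   mu0    1/mm                   linear attenuation coefficient (water)
# Electron and core densities are absolute so that products with microscopic
# cross sections in mm^2 are macroscopic coefficients in 1/mm.

.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305,
        30.974, 32.06, 35.45, 39.948, 39.098, 40.078))

# water reference values (H2O stoichiometry)
.water <- local({
  w <- c(H = 2 * 1.008 / 18.015, O = 15.999 / 18.015)
  ZA <- w[["H"]] * 1 / 1.008 + w[["O"]] * 8 / 15.999
  invA <- w[["H"]] / 1.008 + w[["O"]] / 15.999
  list(ZA = ZA,                       # ~0.5551 electrons/u
       e_per_g = .const$NA_mol * ZA,  # electrons per gram
       n_per_g = .const$NA_mol * invA,# nuclei per gram
       A_m = 1 / invA)                # mean atomic mass, g/mol of atoms
})

#' Load the shipped HU-to-material conversion table
#'
#' Fourteen contiguous HU ranges, each giving the relative proportion by mass
#' of 12 elements plus a linear density interpolation across the range.  The
#' numbers follow the standard stoichiometric air/lung/adipose/soft-tissue/
#' bone ladder; they are a documented default (synthetic, not vendor
#' commissioning data) and can be replaced by the user.
#'
#' @param path Optional path to an alternative CSV with the same columns.
#' @return Data frame with columns `hu_lo`, `hu_hi`, `rho_lo`, `rho_hi` and
#'   the 12 element mass fractions.
#' @export
load_hu_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hu_material_table.csv", package = "ordose")
  }
  tab <- utils::read.csv(path, check.names = FALSE)
  frac <- as.matrix(tab[, .elements$symbol])
  stopifnot(all(abs(rowSums(frac) - 1) < 1e-6))
  tab
}

#' Convert a Hounsfield value to a material sample
#'
#' Categorises the HU value into one of the 14 ranges of the conversion
#' table, interpolates the mass density linearly within the range and
#' computes electron and atomic-core densities from the elemental mass
#' fractions.  HU values outside the table span are clamped to the nearest
#' range (with a warning).
#'
#' @param hu Hounsfield units (scalar).
#' @param table Conversion table from [load_hu_table()].
#' @return A list (`material_sample`): `hu`, `rho` (g/cm^3), `rho_e`
#'   (electrons/mm^3), `rho_e_rel` (relative to water at 1 g/cm^3), `rho_c`
#'   (nuclei/mm^3), `rho_c_rel`, `mass_fractions`, `A_m` (g/mol).
#' @export
hu_to_material <- function(hu, table = load_hu_table()) {
  if (hu < table$hu_lo[1] || hu > table$hu_hi[nrow(table)]) {
    warning(sprintf("HU %g outside table span; clamped", hu))
    hu <- max(table$hu_lo[1], min(hu, table$hu_hi[nrow(table)]))
  }
  i <- max(which(table$hu_lo <= hu))
  i <- min(i, nrow(table))
  row <- table[i, ]
  t <- (hu - row$hu_lo) / (row$hu_hi - row$hu_lo)
  rho <- row$rho_lo + t * (row$rho_hi - row$rho_lo)
  w <- as.numeric(row[.elements$symbol])
  names(w) <- .elements$symbol
  ZA <- sum(w * .elements$Z / .elements$A)
  invA <- sum(w / .elements$A)
  e_per_g <- .const$NA_mol * ZA
  n_per_g <- .const$NA_mol * invA
  rho_g_mm3 <- rho * 1e-3
  structure(list(
    hu = hu, rho = rho,
    rho_e = e_per_g * rho_g_mm3,
    rho_e_rel = (e_per_g * rho) / (.water$e_per_g * 1.0),
    rho_c = n_per_g * rho_g_mm3,
    rho_c_rel = (n_per_g * rho) / (.water$n_per_g * 1.0),
    mass_fractions = w,
    A_m = 1 / invA), class = "material_sample")
}

# absolute electron / core densities of water-equivalent medium of relative
# mass density rho (g/cm^3); used by the solvers for water-scaled phantoms
water_rho_e <- function(rho) .water$e_per_g * rho * 1e-3
water_rho_c <- function(rho) .water$n_per_g * rho * 1e-3

# Sternheimer density-effect correction, water parameterisation
.delta_water <- function(E_MeV, mc2 = .const$mec2) {
  tau <- E_MeV / mc2
  p_over_mc <- sqrt(tau * (tau + 2))
  x <- log10(p_over_mc)
  x0 <- 0.2400; x1 <- 2.8004; C <- -3.5017; a <- 0.09116; m <- 3.4773
  d <- ifelse(x < x0, 0,
       ifelse(x < x1, 4.606 * x + C + a * (x1 - x)^m, 4.606 * x + C))
  pmax(d, 0)
}

#' Electron mass collision stopping power (water)
#'
#' ICRU-style Moller collision stopping power for electrons in water with the
#' Sternheimer density-effect correction (the density-effect medium is water
#' throughout the package).
#'
#' @param E_MeV Kinetic energy in MeV (validity floor 0.01 MeV).
#' @return Stopping power in MeV cm^2/g (vectorised).
#' @export
electron_stopping_power <- function(E_MeV) {
  if (any(E_MeV < 0.01)) stop("electron_stopping_power: E below 0.01 MeV")
  mc2 <- .const$mec2
  tau <- E_MeV / mc2
  beta2 <- tau * (tau + 2) / (tau + 1)^2
  I <- .const$I_water
  Fm <- 1 - beta2 + (tau^2 / 8 - (2 * tau + 1) * log(2)) / (tau + 1)^2
  delta <- .delta_water(E_MeV)
  (.const$K_bethe / 2) * .water$ZA / beta2 *
    (log(tau^2 * (tau + 2) / 2 * (mc2 / I)^2) + Fm - delta)
}

#' Proton mass collision stopping power (water-scaled media)
#'
#' Bethe mass collision stopping power with the water mean excitation energy;
#' shell and density-effect corrections are negligible over 5-250 MeV and are
#' omitted.
#'
#' @param E_MeV Kinetic energy in MeV, within 1-300 MeV.
#' @return Stopping power in MeV cm^2/g (vectorised).
#' @export
proton_stopping_power <- function(E_MeV) {
  if (any(E_MeV < 1 | E_MeV > 300)) stop("proton_stopping_power: E out of range")
  mc2 <- .const$mpc2
  gamma <- 1 + E_MeV / mc2
  beta2 <- 1 - 1 / gamma^2
  Wm <- 2 * .const$mec2 * beta2 * gamma^2   # max energy transfer approx
  .const$K_bethe * .water$ZA / beta2 * (log(Wm / .const$I_water) - beta2)
}

#' CSDA range of protons in water (range-energy relation)
#'
#' Bragg-Kleeman power law `R = alpha * E^p` with the conventional water
#' constants `alpha = 0.0022 cm / MeV^p`, `p = 1.77`.  Agrees with numeric
#' integration of the Bethe stopping power to within a few percent over
#' 50-250 MeV (tested).
#'
#' @param E_MeV Kinetic energy in MeV.
#' @param alpha_cm,p Range-energy constants (configurable).
#' @return Range in mm of water (vectorised).
#' @export
csda_range <- function(E_MeV, alpha_cm = 0.0022, p = 1.77) {
  10 * alpha_cm * E_MeV^p
}

#' Energy whose CSDA range equals a given depth (inverse of [csda_range()])
#' @param R_mm Range in mm of water.
#' @inheritParams csda_range
#' @return Energy in MeV.
#' @export
energy_from_range <- function(R_mm, alpha_cm = 0.0022, p = 1.77) {
  (R_mm / (10 * alpha_cm))^(1 / p)
}

#' Load the shipped photon attenuation table for water
#'
#' Linear attenuation coefficients (1/mm) of water at the photon group
#' energies; Compton-dominated MV range.  Values interpolate log-linearly.
#'
#' @param path Optional alternative CSV (`energy_MeV`, `mu0_per_mm`).
#' @return A function `mu0(E_MeV)` returning 1/mm.
#' @export
load_attenuation_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "attenuation_water.csv", package = "ordose")
  }
  tab <- utils::read.csv(path)
  stopifnot(all(tab$mu0_per_mm > 0), !is.unsorted(tab$energy_MeV))
  function(E_MeV) {
    exp(stats::approx(tab$energy_MeV, log(tab$mu0_per_mm), xout = E_MeV,
                      rule = 2)$y)
  }
}
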