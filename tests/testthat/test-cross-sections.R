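test_that("Compton inverse kinematics matches the closed form", {
  # forward scatter leaves the energy unchanged
  expect_equal(compton_initial_energy(2, 1), 2)
  # backscatter limit E = mec2/2 is singular
  expect_true(is.na(compton_initial_energy(0.2555, -1)))
  # arithmetic oracle: E' = E / (1 - (E/mec2)(1 - cos))
  expect_equal(compton_initial_energy(0.2, 0),
               0.2 / (1 - 0.2 / 0.51099895), tolerance = 1e-12)
  expect_equal(compton_initial_energy(0.2, 0), 0.3287, tolerance = 1e-3)
  # initial energy never below the final energy
  set.seed(3)
  E <- runif(200, 0.1, 5); u <- runif(200, -1, 1)
  Ei <- compton_initial_energy(E, u)
  expect_true(all(is.na(Ei) | Ei >= E - 1e-12))
})

test_that("Klein-Nishina differential has the known limits and total", {
  re2 <- 2.8179403e-12^2
  expect_equal(klein_nishina_differential(5, 1), re2, tolerance = 1e-12)
  expect_equal(klein_nishina_differential(1e-6, 0.3),
               re2 / 2 * (1 + 0.3^2), tolerance = 1e-4)  # Thomson limit
  # total equals numeric quadrature of the differential within 0.1%
  for (E in c(0.5, 2, 10)) {
    num <- stats::integrate(function(u) {
      2 * pi * klein_nishina_differential(E, u)
    }, -1, 1, rel.tol = 1e-10)$value
    expect_equal(klein_nishina_total(E), num, tolerance = 1e-3)
  }
})

test_that("empirical photon factors scale the tables as printed", {
  q <- build_standard_angular_quadrature()
  eg <- build_energy_grid("photon")
  raw <- build_compton_tables(q, eg, factors = NULL)
  sc <- apply_photon_empirical_factors(raw, photon_factors())
  fwd <- raw$cosines >= 1 - 1e-9
  for (g in c(1, 7, 14)) {
    r <- raw$diff_gamma[, , g]; s <- sc$diff_gamma[, , g]
    expect_equal(s[fwd], 2.0 * r[fwd])
    expect_equal(s[!fwd], 10.0 * r[!fwd])
  }
  expect_equal(sc$tot_gamma, 3.0 * raw$tot_gamma)
  expect_error(apply_photon_empirical_factors(sc), "already applied")
  # all stored cross sections non-negative; init energy >= final energy
  expect_true(all(sc$diff_gamma >= 0))
  expect_true(all(sc$diff_e >= 0))
  for (g in seq_len(nrow(eg))) {
    ei <- sc$init_energy[, , g]
    expect_true(all(is.na(ei) | ei >= eg$energy[g] - 1e-12))
  }
})

test_that("Moller tables obey the printed total factor and forward zeroing", {
  q <- build_standard_angular_quadrature()
  eg <- build_energy_grid("electron")
  xs <- build_electron_xs_tables(q, eg)
  wcut <- (eg$upper[1] - eg$lower[1]) / 2
  expect_equal(xs$moller_tot, 8.0e-5 * moller_total0(eg$energy, wcut),
               tolerance = 1e-12)
  # forward (self-pair) entries exactly zero
  fwd <- xs$cosines >= 1 - 1e-9
  for (g in c(1, 8, 14)) {
    expect_true(all(xs$moller_diff[, , g][fwd] == 0))
    expect_true(all(xs$mott_diff[, , g][fwd] == 0))
    expect_true(all(xs$moller_diff[, , g] >= 0))
  }
  # differential in energy is positive over the allowed transfer range
  expect_true(all(moller_differential_energy(2, c(0.3, 0.6, 1.0)) > 0))
  expect_equal(moller_differential_energy(2, 1.5), 0)  # W > E/2
})

test_that("electron Mott total follows the material correction", {
  s0 <- mott_sigma0(1, "electron")
  expect_equal(mott_total_electron(s0), 8.0e-3 * s0, tolerance = 1e-9)
  # with sigma0 = 0 the sign of the material term is visible:
  # heavier-than-water material floors at zero, lighter stays positive
  Aw <- 18.015 / 3  # mean atomic mass of water, g per mol of atoms
  expect_equal(mott_total_electron(0, A_m = Aw), 0)
  expect_equal(mott_total_electron(0, A_m = Aw + 5), 0)      # floored
  expect_gt(mott_total_electron(0, A_m = Aw - 2), 0)
  # bone-like (heavier) total below the water value at equal sigma0
  expect_lte(mott_total_electron(s0, A_m = Aw + 5),
             mott_total_electron(s0, A_m = Aw))
})

test_that("proton Mott scaling interpolates between f_low and f_high", {
  s0 <- 1
  expect_equal(mott_total_proton(s0, 0, 50), 0.8)
  # the index stops at E-1, so the pure f_high limit is never reached
  expect_equal(mott_total_proton(s0, 49, 50), (1 / 50) * 0.8 + (49 / 50) * 0.05)
  v <- mott_total_proton(s0, 0:49, 50)
  expect_true(all(diff(v) < 0))
  expect_error(mott_total_proton(s0, 50, 50))
  expect_error(mott_total_proton(s0, -1, 50))
})

test_that("screened-Rutherford differential integrates to the stated total", {
  # independent oracle on the singularity-free back hemisphere: compare the
  # numeric integral of the differential against the hand closed form
  for (part in c("electron", "proton")) {
    E <- if (part == "electron") 1 else 100
    num <- stats::integrate(function(u) {
      2 * pi * mott_sigma0(E, part, cos_theta = u, differential = TRUE)
    }, -1, 0, rel.tol = 1e-10)$value
    # hand form: per element, 4 pi c [1/(1/2+eta) - 1/(1+eta)] ... via
    # antiderivative of ((1-u)/2 + eta)^-2 over u in [-1, 0]
    scl <- mott_screening_scale(part)
    mc2 <- if (part == "electron") 0.51099895 else 938.27209
    gamma <- 1 + E / mc2
    pc <- mc2 * sqrt(gamma^2 - 1); beta <- pc / (gamma * mc2)
    hand <- 0
    wat <- data.frame(Z = c(1, 8), n = c(2, 1) * 6.02214076e23 / 18.015 * 1e-3)
    for (i in 1:2) {
      chi0 <- (197.32698 / pc) / (0.885 * 52917.7 * wat$Z[i]^(-1 / 3))
      eta <- scl^2 * chi0^2 *
        (1.13 + 3.76 * (wat$Z[i] / 137.036 / beta)^2) / 4
      coef <- wat$n[i] * (wat$Z[i] * 2.8179403e-12 * 0.51099895 / (2 * pc * beta))^2
      hand <- hand + 4 * pi * coef * (1 / (0.5 + eta) - 1 / (1 + eta))
    }
    expect_equal(num, hand, tolerance = 5e-3)
  }
})

test_that("screening calibration anchors are honoured", {
  # electron: corrected water total at 1 MeV equals the reciprocal CSDA range
  R1 <- stats::integrate(function(E) 1 / (electron_stopping_power(E) / 10),
                         0.02, 1)$value
  expect_equal(mott_total_electron(mott_sigma0(1, "electron")), 1 / R1,
               tolerance = 1e-6)
  # proton: tau * sigma_tot = 0.05 in the lowest group
  expect_equal(1e-3 * mott_total_proton(mott_sigma0(5, "proton"), 0, 50),
               0.05, tolerance = 1e-6)
})

test_that("cross-section tables dump to CSV", {
  q <- build_standard_angular_quadrature()
  xs <- build_proton_xs_tables(q, build_energy_grid("proton"))
  d <- file.path(tempdir(), "xsdump")
  xs_tables_to_csv(xs, d)
  tot <- read.csv(file.path(d, "totals.csv"))
  expect_equal(tot$mott_tot, xs$mott_tot)
})
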