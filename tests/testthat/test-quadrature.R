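test_that("standard quadrature has the stated angles, weights and 26 directions", {
  q <- build_standard_angular_quadrature()
  o <- q$ordinates
  expect_setequal(unique(o$gantry_deg),
                  c(0, 47.5, 90, 132.5, 180, 227.5, 270, 312.5))
  expect_setequal(unique(o$couch_deg), c(270, 315, 0, 45))
  # pole rows with couch != 0 carry zero weight, all others 4*pi/32
  pole <- o$gantry_deg %in% c(0, 180)
  expect_true(all(o$weight[pole & o$couch_deg != 0] == 0))
  expect_equal(o$weight[!(pole & o$couch_deg != 0)],
               rep(4 * pi / 32, 26), tolerance = 1e-12)
  expect_true(all(o$weight >= 0))
  # exactly 26 distinct nonzero-weight directions (enumeration oracle:
  # 6 non-pole gantry x 4 couch + 2 poles)
  act <- o[o$weight > 0, ]
  expect_identical(nrow(act), 26L)
  dirs <- as.matrix(act[, c("mu", "eta", "xi")])
  d2 <- as.matrix(dist(dirs))
  expect_true(all(d2[upper.tri(d2)] > 1e-6))
  # unit vectors
  expect_equal(unname(rowSums(dirs^2)), rep(1, 26), tolerance = 1e-12)
  # weighted direction sum vanishes by symmetry
  expect_equal(as.numeric(colSums(dirs * act$weight)), c(0, 0, 0),
               tolerance = 1e-9)
})

test_that("direction mapping is self-consistent and degenerate at the poles", {
  v <- direction_from_angles(0, 90)
  expect_equal(sum(v^2), 1, tolerance = 1e-14)
  expect_equal(abs(v), c(1, 0, 0))          # lateral cardinal direction
  expect_equal(direction_from_angles(0, 0), c(0, 0, 1))
  for (c in c(45, 123, 270)) {
    expect_equal(direction_from_angles(c, 0), direction_from_angles(0, 0))
  }
  # round trip away from the poles
  set.seed(7)
  for (i in 1:50) {
    cc <- runif(1, 0, 360); gg <- runif(1, 5, 175)
    a <- angles_from_direction(direction_from_angles(cc, gg))
    expect_equal(a[["couch_deg"]], cc, tolerance = 1e-9)
    expect_equal(a[["gantry_deg"]], gg, tolerance = 1e-9)
  }
})

test_that("fine quadrature follows the sine weighting", {
  q <- build_fine_angular_quadrature()
  expect_identical(q$n_couch, 18L)
  expect_identical(q$n_gantry, 36L)
  o <- q$ordinates
  w0 <- 2 * pi^2 / (18 * 36)
  expect_equal(w0, 0.030462, tolerance = 1e-4)
  expect_equal(unique(o$weight[o$gantry_deg == 90]), w0, tolerance = 1e-12)
  expect_true(all(o$weight[o$gantry_deg == 180] == 0))
  expect_equal(o$weight,
               ifelse(o$gantry_deg %in% c(0, 180), 0,
                      w0 * abs(sin(o$gantry_deg * pi / 180))),
               tolerance = 1e-12)
})

test_that("energy grids have the stated groups and contiguous boundaries", {
  ph <- build_energy_grid("photon")
  expect_identical(nrow(ph), 14L)
  expect_equal(ph$energy, c(seq(0.5, 4, by = 0.5), 5:10))
  pr <- build_energy_grid("proton")
  expect_identical(nrow(pr), 50L)
  expect_equal(pr$energy, seq(5, 250, by = 5))
  for (g in list(ph, pr)) {
    expect_true(all(diff(g$energy) > 0))
    # boundaries midway and contiguous (no gaps/overlaps)
    expect_equal(g$upper[-nrow(g)], g$lower[-1], tolerance = 1e-12)
    expect_equal(g$upper[-nrow(g)],
                 (g$energy[-1] + g$energy[-nrow(g)]) / 2, tolerance = 1e-12)
    expect_equal(g$f_E, 1 / (g$upper - g$lower), tolerance = 1e-12)
  }
  # a 0.5 MeV wide group has f_E = 2
  expect_equal(ph$f_E[2], 2.0)
  # electron grid reuses the photon grid
  expect_equal(build_energy_grid("electron")$energy, ph$energy)
  expect_error(build_energy_grid("neutron"))
})

test_that("energy_group_of handles cutoff and clamping", {
  g <- build_energy_grid("photon")
  expect_identical(energy_group_of(0.5, g), 1L)
  expect_identical(energy_group_of(0.1, g), 0L)     # below cutoff
  expect_identical(energy_group_of(50, g), nrow(g)) # clamped to top
})

test_that("bilinear beam assignment partitions unity", {
  q <- build_standard_angular_quadrature()
  # exactly on an ordinate
  a <- assign_beam_to_ordinates(0, 90, q)
  expect_equal(sum(a$fraction), 1, tolerance = 1e-12)
  expect_equal(max(a$fraction), 1)
  hit <- q$ordinates[a$ordinate[which.max(a$fraction)], ]
  expect_equal(c(hit$couch_deg, hit$gantry_deg), c(0, 90))
  # midpoint in both angles -> four fractions of 0.25
  b <- assign_beam_to_ordinates((0 + 45) / 2, (47.5 + 90) / 2, q)
  expect_equal(sort(b$fraction), rep(0.25, 4))
  # property: partition of unity over random angles incl. wrap-around
  set.seed(42)
  for (i in 1:1000) {
    x <- assign_beam_to_ordinates(runif(1, 0, 360), runif(1, 0, 360), q)
    expect_true(all(x$fraction >= -1e-12 & x$fraction <= 1 + 1e-12))
    expect_equal(sum(x$fraction), 1, tolerance = 1e-12)
  }
})

test_that("quadrature and energy grids serialise to JSON and back", {
  q <- build_standard_angular_quadrature()
  f <- tempfile(fileext = ".json")
  write_quadrature_json(q, f)
  q2 <- read_quadrature_json(f)
  expect_equal(q2$ordinates$weight, q$ordinates$weight)
  expect_equal(q2$ordinates$mu, q$ordinates$mu)
  g <- build_energy_grid("proton")
  write_quadrature_json(g, f)
  g2 <- read_quadrature_json(f)
  expect_equal(g2$energy, g$energy)
  expect_equal(attr(g2, "particle"), "proton")
})
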