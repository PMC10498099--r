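test_that("sweep_cell implements the hybrid closure", {
  # vacuum streaming: inflow passes through unchanged
  r <- sweep_cell(3.5, 0, 0, 0, 0, c(5, 5, 5), c(1, 0, 0))
  expect_equal(r$center, 3.5)
  expect_equal(r$outflow, rep(3.5, 3))
  # no inflow, no source -> zero
  expect_equal(sweep_cell(0, 0, 0, 0, 0.1, c(5, 5, 5), c(0.6, 0.48, 0.64))$center, 0)
  # source only, sigma = 0
  cosn <- c(0.6, 0.48, 0.64); sp <- c(5, 4, 2)
  r2 <- sweep_cell(0, 0, 0, 2, 0, sp, cosn)
  expect_equal(r2$center, 2 / sum(2 * abs(cosn) / sp), tolerance = 1e-12)
  expect_error(sweep_cell(0, 0, 0, 1, 0, sp, c(0, 0, 0)))
})

test_that("transport_sweep streams losslessly through vacuum and flips with the octant", {
  q <- tiny_quadrature(2)                 # +z and -z ordinates
  ph <- tiny_phantom(4, 5, density = 0)   # vacuum (sigma = 0)
  grid <- ordose:::transport_grid(ph)
  V <- prod(ph$dims)
  src <- matrix(0, 2, V)
  k_first <- function(k) 1 + 0 + 4 * (1 + 4 * (k - 1))  # voxel (1, 2, k)
  src[1, k_first(1)] <- 1                 # +z ordinate: source at k = 1
  src[2, k_first(4)] <- 1                 # -z ordinate: source at k = 4
  out <- transport_sweep(list(src), list(rep(0, V)), grid, q)
  phi <- out[[1]]
  # ordinate 1 (+z): fluence constant downstream of the source; streaming
  # conservation means the chain of centres is exactly constant in vacuum
  v0 <- phi[1, k_first(1)]
  expect_gt(v0, 0)
  expect_equal(phi[1, vapply(1:4, k_first, numeric(1))], rep(v0, 4))
  # ordinate 2 (-z): traversal order flips with the cosine sign, so its
  # source at k = 4 fills k <= 4 and ordinate 1 sees nothing from it
  expect_equal(phi[2, vapply(1:4, k_first, numeric(1))],
               rep(phi[2, k_first(4)], 4))
  expect_gt(phi[2, k_first(1)], 0)
  # nothing upstream of the +z source beyond its own layer
  expect_equal(sum(phi[1, ] > 0), 4L)
})

test_that("iterated sweeps reproduce the assembled linear system", {
  # <= 4x4x4 grid, 4 ordinates, within-group coupling: the source-iterated
  # sweep must converge to the dense solve of (L - S) phi = Q_fix
  set.seed(21)
  q <- tiny_quadrature(4)
  dims <- c(3, 3, 3); V <- prod(dims)
  ph <- make_phantom(rep(15, 3), 5)
  grid <- ordose:::transport_grid(ph)
  dirs <- as.matrix(q$ordinates[, c("mu", "eta", "xi")])
  sigma <- runif(V, 0.05, 0.12)
  # modest coupling so 5 iterations converge well below 0.1%
  C <- matrix(runif(16, 0, 0.002), 4, 4); diag(C) <- 0
  Qfix <- matrix(0, 4, V)
  Qfix[1, sample(V, 5)] <- runif(5, 0.5, 1)
  # dense oracle
  L <- assemble_streaming(dirs, dims, grid$spacing, sigma)
  S <- matrix(0, 4 * V, 4 * V)
  for (n in 1:4) for (np in 1:4) {
    if (C[np, n] > 0) {
      ii <- ((n - 1) * V + 1):(n * V)
      jj <- ((np - 1) * V + 1):(np * V)
      S[cbind(ii, jj)] <- C[np, n]
    }
  }
  phi_direct <- solve(L - S, as.numeric(t(Qfix)))
  # package path: iterate sweep with source rebuilt from current fluence
  phi <- matrix(0, 4, V)
  for (it in 1:5) {
    Q <- Qfix + crossprod(C, phi)
    phi <- transport_sweep(list(Q), list(sigma), grid, q)[[1]]
  }
  ref <- vec_to_tensor(phi_direct, 4, V)
  nz <- ref > 1e-12
  expect_lt(max(abs(phi[nz] - ref[nz]) / ref[nz]), 1e-3)
})

test_that("scatter sources match the brute-force double sum", {
  q <- tiny_quadrature(4)
  eg <- build_energy_grid("photon")
  tabs <- build_compton_tables(q, eg)
  V <- 6
  set.seed(9)
  fl <- lapply(seq_len(nrow(eg)), function(g) matrix(runif(4 * V), 4, V))
  rho_e <- runif(V, 1e20, 4e20)
  w <- ordose:::active_ordinates(q)$weight
  got <- photon_scatter_source(fl, tabs, rho_e, q)
  want <- brute_force_source(fl, tabs$diff_gamma, tabs$init_group, w, rho_e)
  for (g in seq_along(want)) {
    if (is.null(got[[g]])) {
      expect_equal(max(abs(want[[g]])), 0)
    } else {
      expect_equal(got[[g]], want[[g]], tolerance = 1e-12)
    }
  }
  # electron fixed source against the same oracle
  gote <- electron_fixed_source(fl, tabs, rho_e, q)
  wante <- brute_force_source(fl, tabs$diff_e, tabs$init_group_e, w, rho_e)
  for (g in seq_along(wante)) {
    if (is.null(gote[[g]])) {
      expect_equal(max(abs(wante[[g]])), 0)
    } else {
      expect_equal(gote[[g]], wante[[g]], tolerance = 1e-12)
    }
  }
  # zero fluence and vacuum give a zero source
  fl0 <- lapply(fl, function(m) m * 0)
  expect_true(all(vapply(photon_scatter_source(fl0, tabs, rho_e, q),
                         function(m) is.null(m) || all(m == 0), logical(1))))
  expect_true(all(vapply(electron_fixed_source(fl, tabs, rho_e * 0, q),
                         function(m) is.null(m) || all(m == 0), logical(1))))
})

test_that("photon solve: zero input, vacuum transparency, convergence", {
  q <- build_standard_angular_quadrature()
  eg <- build_energy_grid("photon")
  tabs <- build_compton_tables(q, eg)
  ph <- make_phantom(c(60, 60, 100), 10)
  grid <- ordose:::transport_grid(ph)
  V <- prod(ph$dims)
  N <- nrow(ordose:::active_ordinates(q))
  zero <- lapply(seq_len(nrow(eg)), function(g) matrix(0, N, V))
  r0 <- solve_photon_transport(zero, tabs, grid, q, iterations = 2)
  expect_true(all(vapply(r0$total, function(m) all(m == 0), logical(1))))
  # vacuum phantom: total equals unscattered after any number of iterations
  vac <- make_phantom(c(60, 60, 100), 10, density = 0)
  gvac <- ordose:::transport_grid(vac)
  beam <- beam_config("photon", ssd_mm = 950)
  un_vg <- photon_unscattered_fluence(beam, vac, eg)
  un <- distribute_unscattered(un_vg, beam, q, vac)
  rv <- solve_photon_transport(un, tabs, gvac, q, iterations = 3)
  for (g in seq_along(un)) expect_equal(rv$total[[g]], un[[g]])
  # water: iteration 5 within 1% of iteration 10 at the beam centre
  un_w <- distribute_unscattered(photon_unscattered_fluence(beam, ph, eg),
                                 beam, q, ph)
  probe <- (5 - 1) * 36 + (3 - 1) * 6 + 3
  r10 <- solve_photon_transport(un_w, tabs, grid, q, iterations = 10,
                                probes = probe)
  tr <- r10$trace[, 1]
  expect_lt(abs(tr[5] - tr[10]) / tr[10], 0.01)
  # convergence monotonicity under non-negative sources
  expect_true(all(diff(tr) >= -1e-12))
  # non-negativity of the final fluence
  expect_true(all(vapply(r10$total, function(m) all(m >= 0), logical(1))))
})

test_that("electron solve: zero source, decay from a point source, convergence", {
  q <- build_standard_angular_quadrature()
  eg <- build_energy_grid("electron")
  xs <- build_electron_xs_tables(q, eg)
  ph <- make_phantom(c(60, 60, 60), 10)
  grid <- ordose:::transport_grid(ph)
  V <- prod(ph$dims); N <- nrow(ordose:::active_ordinates(q))
  zero <- lapply(seq_len(nrow(eg)), function(g) matrix(0, N, V))
  r0 <- solve_electron_transport(zero, xs, grid, q, iterations = 2)
  expect_true(all(vapply(r0$total, function(m) is.null(m) || all(m == 0),
                         logical(1))))
  # central point source: fluence decays monotonically along an ordinate
  qf <- zero
  ctr <- c(3, 3, 3)
  vctr <- (ctr[3] - 1) * 36 + (ctr[2] - 1) * 6 + ctr[1]
  o <- ordose:::active_ordinates(q)
  n_up <- which(o$gantry_deg == 0 & o$couch_deg == 0)  # +z ordinate
  qf[[6]][n_up, vctr] <- 1
  r <- solve_electron_transport(qf, xs, grid, q, iterations = 5,
                                probes = vctr)
  vk <- function(k) (k - 1) * 36 + (ctr[2] - 1) * 6 + ctr[1]
  line <- r$total[[6]][n_up, vapply(3:6, vk, numeric(1))]
  expect_true(all(diff(line) < 0))
  expect_true(all(line > 0))
  # iteration 5 vs 10 within 1% at the source voxel
  r10 <- solve_electron_transport(qf, xs, grid, q, iterations = 10,
                                  probes = vctr)
  tr <- r10$trace[, 1]
  expect_lt(abs(tr[5] - tr[10]) / tr[10], 0.01)
})

test_that("proton solve: no scatter without tau, non-negative, spreading", {
  q <- build_standard_angular_quadrature()
  eg <- build_energy_grid("proton")
  xs <- build_proton_xs_tables(q, eg)
  ph <- make_phantom(c(60, 60, 120), 10)
  grid <- ordose:::transport_grid(ph)
  lay <- sobp_layer_weights(40, 80, 10)
  beam <- beam_config("proton", layers = lay, ssd_mm = 2200)
  un_vg <- proton_unscattered_fluence(beam, ph, eg, xs)
  un <- distribute_unscattered(un_vg, beam, q, ph)
  # tau = 0: no scattered fluence is generated, total equals unscattered
  r0 <- solve_proton_transport(un, xs, grid, q, iterations = 3, tau = 0)
  for (g in seq_along(un)) {
    if (!is.null(r0$total[[g]])) expect_equal(r0$total[[g]], un[[g]])
  }
  # tau > 0: scattered fluence appears, everything non-negative
  r1 <- solve_proton_transport(un, xs, grid, q, iterations = 3, tau = 1e-3)
  sc_tot <- sum(vapply(r1$scattered, function(m) if (is.null(m)) 0 else sum(m),
                       numeric(1)))
  expect_gt(sc_tot, 0)
  expect_true(all(vapply(r1$total, function(m) is.null(m) || all(m >= 0),
                         logical(1))))
  # groupwise solver agrees with the tensor solver
  gw <- ordose:::solve_proton_groupwise(un_vg, beam, q, grid, xs,
                                        iterations = 3)
  V <- prod(ph$dims)
  expect_equal(gw$phi_scalar, ordose:::tensor_scalar(r1$total, V),
               tolerance = 1e-10)
})

test_that("adaptive mask merges only low-fluence full clusters", {
  ph <- make_phantom(c(80, 80, 80), 5)   # 16^3 voxels, 4^3 supercells
  grid <- ordose:::transport_grid(ph)
  V <- prod(ph$dims)
  # uniform fluence: nothing merged
  m1 <- build_adaptive_mask(matrix(1, V, 1), grid, "photon")
  expect_false(any(m1$merged))
  # fluence confined to a central column: outside clusters merged
  arr <- array(0, ph$dims); arr[7:10, 7:10, ] <- 1
  m2 <- build_adaptive_mask(matrix(as.numeric(arr), V, 1), grid, "proton")
  expect_true(any(m2$merged))
  merged_arr <- array(m2$merged, m2$scdims)
  expect_false(any(merged_arr[2:3, 2:3, ]))   # the column stays unmerged
  expect_true(all(merged_arr[1, 1, ]))
  # partial clusters at the edge are never merged
  ph2 <- make_phantom(c(50, 50, 50), 5)       # 10 voxels: 2 full + 1 partial
  g2 <- ordose:::transport_grid(ph2)
  m3 <- build_adaptive_mask(matrix(0, prod(ph2$dims), 1) + 1e-9, g2, "photon")
  expect_false(any(array(m3$merged, m3$scdims)[3, , ]))
})

test_that("adaptive sweep equals the coarse solve on fully merged grids", {
  # all-false mask: bitwise identical to the full-resolution sweep
  set.seed(1)
  q <- tiny_quadrature(4)
  ph <- make_phantom(c(40, 40, 40), 5)
  grid <- ordose:::transport_grid(ph)
  V <- prod(ph$dims)
  dirs <- as.matrix(q$ordinates[, c("mu", "eta", "xi")])
  Q <- matrix(runif(4 * V), 4, V)
  sig <- runif(V, 0, 0.05)
  full <- ordose:::cpp_sweep_group(Q, sig, grid$dims, grid$spacing, dirs)
  ad0 <- ordose:::cpp_sweep_group_adaptive(Q, sig, grid$dims, grid$spacing,
                                           dirs, rep(FALSE, 8), c(2L, 2L, 2L))
  expect_identical(ad0, full)
  # fully merged grid with uniform per-cluster sources: equals the coarse
  # 2x2x2 sweep at quadruple spacing, replicated to the native voxels
  Qc <- matrix(runif(4 * 8), 4, 8)
  sigc <- runif(8, 0, 0.05)
  expand <- function(v) {
    a <- array(v, c(2, 2, 2))
    b <- array(0, c(8, 8, 8))
    for (ci in 1:2) for (cj in 1:2) for (ck in 1:2) {
      b[(ci - 1) * 4 + 1:4, (cj - 1) * 4 + 1:4, (ck - 1) * 4 + 1:4] <-
        a[ci, cj, ck]
    }
    as.numeric(b)
  }
  Qf <- t(apply(Qc, 1, expand))
  sigf <- expand(sigc)
  adm <- ordose:::cpp_sweep_group_adaptive(Qf, sigf, c(8L, 8L, 8L),
                                           c(5, 5, 5), dirs,
                                           rep(TRUE, 8), c(2L, 2L, 2L))
  coarse <- ordose:::cpp_sweep_group(Qc, sigc, c(2L, 2L, 2L), c(20, 20, 20),
                                     dirs)
  for (n in 1:4) {
    expect_equal(adm[n, ], expand(coarse[n, ]), tolerance = 1e-12)
  }
})
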