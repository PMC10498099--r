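# Iterative discrete-ordinates solvers: scatter-source accumulation,
# octant-ordered transport sweeps (hybrid diamond/step closure), photon ->
# electron chaining, proton elastic transport and adaptive voxel coarsening.
#
# Fluence tensors are lists over energy groups of N x V matrices (N active
# ordinates, V voxels, column-major); NULL entries mean identically zero.
# Scatter sources are rebuilt once per group within each iteration, with
# groups processed in descending energy so that down-scatter reads the
# current iteration's higher-group fluence.

# transport-grid view of a phantom: flat density vectors
transport_grid <- function(phantom) {
  list(dims = phantom$dims, spacing = phantom$spacing,
       rho = as.numeric(phantom$rho),
       rho_e_abs = water_rho_e(1) * as.numeric(phantom$rho_e_rel),
       rho_c_rel = as.numeric(phantom$rho_c_rel))
}

#' Solve a single transport cell (hybrid diamond/step closure)
#'
#' Centre fluence from the three upwind inflow faces, the source and the
#' macroscopic removal; the outflow faces equal the centre value (step
#' closure), so the returned `outflow` repeats the centre.
#'
#' @param inflow_x,inflow_y,inflow_z Upwind face fluences.
#' @param Q Source in the cell.
#' @param sigma Macroscopic removal cross section, 1/mm.
#' @param spacings `c(dx, dy, dz)` in mm.
#' @param cosines `c(mu, eta, xi)` direction cosines (signs ignored; the
#'   caller orients the faces upwind).
#' @return List with `center` and `outflow` (length 3).
#' @export
sweep_cell <- function(inflow_x, inflow_y, inflow_z, Q, sigma, spacings,
                       cosines) {
  a <- 2 * abs(cosines) / spacings
  if (sum(a) <= 0) stop("all three direction cosines are zero")
  centre <- (a[1] * inflow_x + a[2] * inflow_y + a[3] * inflow_z + Q) /
    (sum(a) + sigma)
  list(center = centre, outflow = rep(centre, 3))
}

#' One full transport sweep over all ordinates and groups
#'
#' Sweeps every active ordinate of the quadrature through the grid in the
#' octant order determined by its cosine signs, for each energy group in
#' descending order, with vacuum (zero-inflow) boundaries.  Sources are held
#' fixed; with the step closure a single pass solves each group exactly for
#' the given sources.
#'
#' @param sources Fluence-source list over groups of N x V matrices (or
#'   NULL entries).
#' @param sigma_groups List over groups of V-vector macroscopic removal.
#' @param grid From [transport_grid()].
#' @param quadrature An `angular_quadrature`.
#' @param adaptive Optional `adaptive_mask` from [build_adaptive_mask()].
#' @return Fluence tensor (list over groups of N x V matrices).
#' @export
transport_sweep <- function(sources, sigma_groups, grid, quadrature,
                            adaptive = NULL) {
  o <- active_ordinates(quadrature)
  dirs <- as.matrix(o[, c("mu", "eta", "xi")])
  G <- length(sources)
  out <- vector("list", G)
  for (g in rev(seq_len(G))) {
    Q <- sources[[g]]
    if (is.null(Q) || !any(Q != 0)) next
    out[[g]] <- if (is.null(adaptive)) {
      cpp_sweep_group(Q, sigma_groups[[g]], grid$dims, grid$spacing, dirs)
    } else {
      cpp_sweep_group_adaptive(Q, sigma_groups[[g]], grid$dims,
                               grid$spacing, dirs, adaptive$merged,
                               adaptive$scdims)
    }
  }
  structure(out, dims = grid$dims, class = "fluence_tensor")
}

# add two group-tensors (NULL = zero)
tensor_add <- function(a, b) {
  G <- max(length(a), length(b))
  out <- vector("list", G)
  for (g in seq_len(G)) {
    x <- if (g <= length(a)) a[[g]] else NULL
    y <- if (g <= length(b)) b[[g]] else NULL
    out[[g]] <- if (is.null(x)) y else if (is.null(y)) x else x + y
  }
  attributes(out) <- attributes(a)
  out
}

# sum over ordinates -> V x G matrix of scalar fluence
tensor_scalar <- function(tensor, V) {
  G <- length(tensor)
  out <- matrix(0, V, G)
  for (g in seq_len(G)) {
    if (!is.null(tensor[[g]])) out[, g] <- colSums(tensor[[g]])
  }
  out
}

# ---- scatter sources -------------------------------------------------------

# coupling matrices for a (differential table, init-group table) pair:
# per final group g, a list mapping initial group g' to the N x N matrix
# C[n', n] = w[n'] * sigma_diff[n', n, g]  (restricted to entries whose
# kinematic initial group is g'); Q_g = rho * crossprod(C, Phi_{g'})
.coupling_matrices <- function(diff_tab, init_tab, weights) {
  G <- dim(diff_tab)[3]
  out <- vector("list", G)
  for (g in seq_len(G)) {
    ig <- init_tab[, , g]
    sig <- diff_tab[, , g] * weights          # rows n' scaled by w[n']
    gps <- sort(unique(ig[ig > 0 & sig != 0]))
    lst <- list()
    for (gp in gps) {
      C <- sig * (ig == gp)
      if (any(C != 0)) lst[[as.character(gp)]] <- C
    }
    out[[g]] <- lst
  }
  out
}

#' Photon Compton scatter source
#'
#' Discrete collapse of the Compton scatter integral: for each ordinate and
#' final group, a weighted sum over source ordinates of the differential
#' cross section times the fluence in the kinematically-mapped initial
#' group; kinematically impossible transitions contribute nothing.
#'
#' @param fluence Photon fluence tensor (list over groups of N x V).
#' @param tables `compton_tables` built on the same quadrature.
#' @param rho_e Absolute electron density per voxel (length V).
#' @param quadrature The `angular_quadrature` used for the tables.
#' @return Source list over groups of N x V matrices.
#' @export
photon_scatter_source <- function(fluence, tables, rho_e, quadrature) {
  w <- active_ordinates(quadrature)$weight
  cpl <- .coupling_matrices(tables$diff_gamma, tables$init_group, w)
  .apply_coupling(fluence, cpl, rho_e)
}

.apply_coupling <- function(fluence, cpl, rho) {
  G <- length(cpl)
  out <- vector("list", G)
  for (g in seq_len(G)) {
    acc <- NULL
    for (gp_name in names(cpl[[g]])) {
      gp <- as.integer(gp_name)
      phi <- if (gp <= length(fluence)) fluence[[gp]] else NULL
      if (is.null(phi)) next
      term <- crossprod(cpl[[g]][[gp_name]], phi)
      acc <- if (is.null(acc)) term else acc + term
    }
    if (!is.null(acc)) out[[g]] <- sweep(acc, 2, rho, "*")
  }
  out
}

#' Fixed electron source from the photon fluence (Compton recoil)
#'
#' First integral of the electron transport equation as a discrete sum with
#' the photon-to-electron kinematic mapping.
#'
#' @param photon_fluence Total photon fluence tensor.
#' @param tables `compton_tables` (recoil part).
#' @param rho_e Absolute electron density (length V).
#' @param quadrature The `angular_quadrature`.
#' @return Source list over electron groups of N x V matrices.
#' @export
electron_fixed_source <- function(photon_fluence, tables, rho_e,
                                  quadrature) {
  w <- active_ordinates(quadrature)$weight
  cpl <- .coupling_matrices(tables$diff_e, tables$init_group_e, w)
  .apply_coupling(photon_fluence, cpl, rho_e)
}

# ---- solvers ---------------------------------------------------------------

#' Solve the photon transport equations
#'
#' Iterates (default five times): rebuild the Compton scatter source from
#' the current total fluence, sweep the scattered fluence, and add the
#' unscattered fluence back (the unscattered component is fixed).
#'
#' @param unscattered Unscattered photon fluence tensor from
#'   [distribute_unscattered()].
#' @param tables `compton_tables`.
#' @param grid From [transport_grid()].
#' @param quadrature The `angular_quadrature`.
#' @param iterations Number of transport sweeps (default 5).
#' @param adaptive Optional `adaptive_mask`.
#' @param probes Optional voxel indices at which per-iteration scalar
#'   fluence is recorded.
#' @return List: `total` (fluence tensor), `scattered`, `trace` (iteration
#'   x probe matrix of summed fluence), `iterations`.
#' @export
solve_photon_transport <- function(unscattered, tables, grid, quadrature,
                                   iterations = 5, adaptive = NULL,
                                   probes = NULL) {
  G <- length(unscattered)
  sigma <- lapply(seq_len(G), function(g) grid$rho_e_abs * tables$tot_gamma[g])
  scattered <- vector("list", G)
  total <- unscattered
  w <- active_ordinates(quadrature)$weight
  cpl <- .coupling_matrices(tables$diff_gamma, tables$init_group, w)
  trace <- NULL
  for (it in seq_len(iterations)) {
    Q <- .apply_coupling(total, cpl, grid$rho_e_abs)
    scattered <- transport_sweep(Q, sigma, grid, quadrature, adaptive)
    total <- tensor_add(scattered, unscattered)
    if (!is.null(probes)) {
      trace <- rbind(trace, .probe_fluence(total, probes))
    }
  }
  list(total = total, scattered = scattered, trace = trace,
       iterations = iterations)
}

.probe_fluence <- function(tensor, probes) {
  v <- numeric(length(probes))
  for (g in seq_along(tensor)) {
    if (!is.null(tensor[[g]])) v <- v + colSums(tensor[[g]][, probes,
                                                            drop = FALSE])
  }
  v
}

#' Solve the electron transport equations
#'
#' The fixed (Compton) sources are added to the Moller and Mott scatter
#' sources on the right-hand side; the removal term combines the corrected
#' Moller and Mott totals.  Five iterations by default.
#'
#' @param Q_fix Fixed source list from [electron_fixed_source()].
#' @param xs `electron_xs_tables`.
#' @param grid From [transport_grid()].
#' @param quadrature The `angular_quadrature`.
#' @inheritParams solve_photon_transport
#' @return List: `total`, `trace`, `iterations`.
#' @export
solve_electron_transport <- function(Q_fix, xs, grid, quadrature,
                                     iterations = 5, adaptive = NULL,
                                     probes = NULL) {
  G <- length(Q_fix)
  sigma <- lapply(seq_len(G), function(g) {
    grid$rho_e_abs * xs$moller_tot[g] +
      grid$rho_c_rel * xs$mott_tot_water[g]
  })
  w <- active_ordinates(quadrature)$weight
  cpl_m <- .coupling_matrices(xs$moller_diff, xs$moller_init_group, w)
  # Mott: elastic, within-group coupling matrices
  mott <- lapply(seq_len(G), function(g) xs$mott_diff[, , g] * w)
  total <- vector("list", G)
  trace <- NULL
  for (it in seq_len(iterations)) {
    Q <- .apply_coupling(total, cpl_m, grid$rho_e_abs)
    for (g in seq_len(G)) {
      if (!is.null(total[[g]])) {
        mt <- sweep(crossprod(mott[[g]], total[[g]]), 2, grid$rho_c_rel, "*")
        Q[[g]] <- if (is.null(Q[[g]])) mt else Q[[g]] + mt
      }
      if (!is.null(Q_fix[[g]])) {
        Q[[g]] <- if (is.null(Q[[g]])) Q_fix[[g]] else Q[[g]] + Q_fix[[g]]
      }
    }
    total <- transport_sweep(Q, sigma, grid, quadrature, adaptive)
    if (!is.null(probes)) trace <- rbind(trace, .probe_fluence(total, probes))
  }
  list(total = total, trace = trace, iterations = iterations)
}

#' Solve the proton transport equations
#'
#' The unscattered (CSDA) fluence is fixed; the elastic Mott scatter source
#' is rebuilt each iteration from the scattered fluence plus the tau-scaled
#' unscattered fluence (the fluence removed from the primaries by the
#' elastic-loss term is what seeds the scattered field, so `tau = 0`
#' generates no scatter), the scattered fluence is swept, and the total is
#' scattered plus unscattered.  The removal term uses the core density
#' times the energy-scaled Mott total (the printed equation carries a
#' Compton term here, an evident typographical carry-over that this
#' implementation replaces; see the methods vignette).
#'
#' @param unscattered Unscattered proton fluence tensor.
#' @param xs `proton_xs_tables`.
#' @param grid From [transport_grid()].
#' @param quadrature The `angular_quadrature`.
#' @param tau Elastic fluence-loss coefficient seeding the scattered field
#'   (default 1e-3, the beam-model value).
#' @inheritParams solve_photon_transport
#' @return List: `total`, `scattered`, `trace`, `iterations`.
#' @export
solve_proton_transport <- function(unscattered, xs, grid, quadrature,
                                   iterations = 5, adaptive = NULL,
                                   probes = NULL, tau = 1e-3) {
  G <- length(unscattered)
  active <- which(!vapply(unscattered, is.null, logical(1)))
  sigma <- vector("list", G)
  for (g in active) sigma[[g]] <- grid$rho_c_rel * xs$mott_tot[g]
  w <- active_ordinates(quadrature)$weight
  mott <- lapply(seq_len(G), function(g) xs$mott_diff[, , g] * w)
  scattered <- vector("list", G)
  total <- unscattered
  trace <- NULL
  for (it in seq_len(iterations)) {
    Q <- vector("list", G)
    for (g in active) {
      feed <- tau * unscattered[[g]]
      if (!is.null(scattered[[g]])) feed <- feed + scattered[[g]]
      Q[[g]] <- sweep(crossprod(mott[[g]], feed), 2, grid$rho_c_rel, "*")
    }
    scattered <- transport_sweep(Q, sigma, grid, quadrature, adaptive)
    total <- tensor_add(scattered, unscattered)
    if (!is.null(probes)) trace <- rbind(trace, .probe_fluence(total, probes))
  }
  list(total = total, scattered = scattered, trace = trace,
       iterations = iterations)
}

# Memory-lean groupwise proton solve.  Proton elastic (Mott) scattering is
# within-group, so the groups decouple and can be solved one at a time: the
# V x G unscattered fluence is expanded onto the beam ordinates per group,
# iterated, reduced to scalar (ordinate-summed) fluence and discarded.
# Identical results to solve_proton_transport at a fraction of the memory.
solve_proton_groupwise <- function(unscat_vg, beam, quadrature, grid, xs,
                                   iterations = 5, adaptive = NULL,
                                   probes = NULL, S_dose = NULL,
                                   tau = beam$tau) {
  o <- active_ordinates(quadrature)
  dirs <- as.matrix(o[, c("mu", "eta", "xi")])
  w <- o$weight
  asg <- assign_beam_to_ordinates(beam$couch_deg, beam$gantry_deg, quadrature)
  act <- match(asg$ordinate, o$index)
  keep <- !is.na(act)
  asg <- asg[keep, , drop = FALSE]; act <- act[keep]
  V <- nrow(unscat_vg); N <- nrow(o); G <- ncol(unscat_vg)
  phi_scalar <- matrix(0, V, G)
  trace <- if (!is.null(probes)) matrix(0, iterations, length(probes))
  for (g in seq_len(G)) {
    col <- unscat_vg[, g]
    if (!any(col != 0)) next
    unscat_g <- matrix(0, N, V)
    for (q in seq_along(act)) {
      unscat_g[act[q], ] <- unscat_g[act[q], ] + asg$fraction[q] * col
    }
    sigma_g <- grid$rho_c_rel * xs$mott_tot[g]
    mott_g <- xs$mott_diff[, , g] * w
    scat_g <- NULL
    tot_g <- unscat_g
    for (it in seq_len(iterations)) {
      feed <- tau * unscat_g
      if (!is.null(scat_g)) feed <- feed + scat_g
      Q <- sweep(crossprod(mott_g, feed), 2, grid$rho_c_rel, "*")
      scat_g <- if (is.null(adaptive)) {
        cpp_sweep_group(Q, sigma_g, grid$dims, grid$spacing, dirs)
      } else {
        cpp_sweep_group_adaptive(Q, sigma_g, grid$dims, grid$spacing, dirs,
                                 adaptive$merged, adaptive$scdims)
      }
      tot_g <- scat_g + unscat_g
      if (!is.null(probes)) {
        wgt <- if (is.null(S_dose)) 1 else S_dose[g]
        trace[it, ] <- trace[it, ] +
          wgt * colSums(tot_g[, probes, drop = FALSE])
      }
    }
    phi_scalar[, g] <- colSums(tot_g)
  }
  list(phi_scalar = phi_scalar, trace = trace, iterations = iterations)
}

# dose from ordinate-summed (scalar) fluence
.dose_from_scalar <- function(phi_scalar, S, phantom) {
  rho <- as.numeric(phantom$rho)
  vac <- rho <= 0
  d <- as.numeric(phi_scalar %*% S[seq_len(ncol(phi_scalar))])
  d[!vac] <- d[!vac] / rho[!vac]
  d[vac] <- 0
  structure(list(dose = array(d, phantom$dims), dims = phantom$dims,
                 spacing = phantom$spacing,
                 vacuum = array(vac, phantom$dims),
                 normalisation = NA_real_),
            class = "dose_grid")
}

# ---- adaptive mask ---------------------------------------------------------

#' Build the adaptive voxel-coarsening mask
#'
#' Clusters of 4 x 4 x 4 native voxels whose maximum unscattered fluence is
#' below the particle-specific threshold (photons 20%, protons 5%) of the
#' global maximum are merged into single coarse voxels during sweeps.
#' Partial clusters at grid edges are never merged.
#'
#' @param unscattered V x G matrix of unscattered fluence (before ordinate
#'   distribution) or a fluence tensor.
#' @param grid From [transport_grid()] (for the dimensions).
#' @param particle `"photon"` or `"proton"`.
#' @return An `adaptive_mask`: list with `merged` (logical, column-major
#'   over supercells), `scdims`, `threshold`.
#' @export
build_adaptive_mask <- function(unscattered, grid,
                                particle = c("photon", "proton")) {
  particle <- match.arg(particle)
  thr <- if (particle == "photon") 0.20 else 0.05
  V <- prod(grid$dims)
  tot <- if (is.matrix(unscattered)) {
    rowSums(unscattered)
  } else {
    rowSums(tensor_scalar(unscattered, V))
  }
  arr <- array(tot, grid$dims)
  sc <- ceiling(grid$dims / 4)
  merged <- array(FALSE, sc)
  gmax <- max(arr)
  for (ci in seq_len(sc[1])) for (cj in seq_len(sc[2])) for (ck in seq_len(sc[3])) {
    i <- ((ci - 1) * 4 + 1):min(ci * 4, grid$dims[1])
    j <- ((cj - 1) * 4 + 1):min(cj * 4, grid$dims[2])
    k <- ((ck - 1) * 4 + 1):min(ck * 4, grid$dims[3])
    full <- length(i) == 4 && length(j) == 4 && length(k) == 4
    merged[ci, cj, ck] <- full && max(arr[i, j, k]) < thr * gmax
  }
  structure(list(merged = as.logical(merged), scdims = as.integer(sc),
                 threshold = thr), class = "adaptive_mask")
}
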