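# Shared fixtures: tiny quadratures, phantoms and brute-force oracles used
# across test files.  Everything is built in code; no stored data.

# a hand-made quadrature with a few ordinates for solver-scale oracle tests
tiny_quadrature <- function(n = 4) {
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
                c(0.6, 0.48, 0.64))[seq_len(n), , drop = FALSE]
  ang <- t(apply(dirs, 1, ordose::angles_from_direction))
  ords <- data.frame(couch_deg = ang[, 1], gantry_deg = ang[, 2],
                     mu = dirs[, 1], eta = dirs[, 2], xi = dirs[, 3],
                     weight = 4 * pi / n)
  structure(list(ordinates = ords, kind = "standard",
                 n_couch = 1L, n_gantry = n),
            class = "angular_quadrature")
}

# small water phantom for solver tests
tiny_phantom <- function(n = 4, voxel = 5, density = 1.0) {
  make_phantom(rep(n * voxel, 3), voxel, density = density)
}

# brute-force application of a differential table with kinematic group
# mapping: the independent oracle for the coupling machinery
brute_force_source <- function(fluence, diff_tab, init_tab, weights, rho) {
  N <- dim(diff_tab)[1]; G <- dim(diff_tab)[3]
  V <- ncol(fluence[[which(!vapply(fluence, is.null, logical(1)))[1]]])
  out <- vector("list", G)
  for (g in seq_len(G)) {
    Q <- matrix(0, N, V)
    for (n in seq_len(N)) {
      for (np in seq_len(N)) {
        gp <- init_tab[np, n, g]
        if (gp < 1 || gp > length(fluence) || is.null(fluence[[gp]])) next
        Q[n, ] <- Q[n, ] + weights[np] * diff_tab[np, n, g] * fluence[[gp]][np, ]
      }
    }
    out[[g]] <- sweep(Q, 2, rho, "*")
  }
  out
}

# dense assembly of the per-ordinate streaming operator (hybrid
# diamond/step closure, vacuum boundaries) for the linear-system oracle:
# row (n, v): (ax+ay+az+sigma) phi_v - ax phi_upwind_x - ... = Q_v
assemble_streaming <- function(dirs, dims, spacing, sigma) {
  N <- nrow(dirs); V <- prod(dims)
  A <- matrix(0, N * V, N * V)
  idx <- function(n, i, j, k) {
    (n - 1) * V + (i - 1) + dims[1] * ((j - 1) + dims[2] * (k - 1)) + 1
  }
  for (n in seq_len(N)) {
    a <- 2 * abs(dirs[n, ]) / spacing
    s <- sign(dirs[n, ]); s[s == 0] <- 1
    for (k in seq_len(dims[3])) for (j in seq_len(dims[2])) for (i in seq_len(dims[1])) {
      row <- idx(n, i, j, k)
      A[row, row] <- sum(a) + sigma[(i - 1) + dims[1] * ((j - 1) +
                                                         dims[2] * (k - 1)) + 1]
      up <- list(c(i - s[1], j, k), c(i, j - s[2], k), c(i, j, k - s[3]))
      for (d in 1:3) {
        u <- up[[d]]
        if (a[d] > 0 && all(u >= 1) && all(u <= dims)) {
          A[row, idx(n, u[1], u[2], u[3])] <- -a[d]
        }
      }
    }
  }
  A
}

# flatten a fluence tensor (list of N x V) into the (n, v) vector ordering
# used by assemble_streaming
tensor_to_vec <- function(tensor_g) as.numeric(t(tensor_g))
vec_to_tensor <- function(x, N, V) matrix(x, N, V, byrow = TRUE)
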