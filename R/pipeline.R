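# End-to-end dose calculation pipeline and the command-line interface.

#' Full discrete-ordinates dose calculation
#'
#' Runs the complete chain for one beam on one phantom: unscattered-fluence
#' generation, distribution over ordinates (and uncertainty-kernel offsets),
#' optional adaptive coarsening, the iterative transport solve (photons
#' chain into the electron stage) and dose scoring.
#'
#' @param phantom A `voxel_phantom`.
#' @param beam A `beam_config` (its `particle` selects the chain).
#' @param quadrature `"standard"`, `"fine"`, or an `angular_quadrature`.
#' @param iterations Transport iterations (default 5).
#' @param adaptive Use adaptive 4x4x4 voxel merging?
#' @param kernel Optional `uncertainty_kernel`.
#' @param probes Optional voxel indices for convergence traces.
#' @return List: `dose` (`dose_grid`), `fluence` (charged-particle tensor),
#'   `photon_fluence` (photon runs), `trace`, `beam`, `phantom`, timings.
#' @export
calc_dose <- function(phantom, beam, quadrature = "standard",
                      iterations = 5, adaptive = FALSE, kernel = NULL,
                      probes = NULL) {
  t0 <- proc.time()[["elapsed"]]
  quad <- if (is.character(quadrature)) {
    switch(match.arg(quadrature, c("standard", "fine")),
           standard = build_standard_angular_quadrature(),
           fine = build_fine_angular_quadrature())
  } else quadrature
  grid <- transport_grid(phantom)
  timings <- c()
  if (beam$particle == "photon") {
    eg <- build_energy_grid("photon")
    tables <- build_compton_tables(quad, eg)
    unscat_vg <- photon_unscattered_fluence(beam, phantom, eg)
    mask <- if (adaptive) build_adaptive_mask(unscat_vg, grid, "photon")
    unscat <- distribute_unscattered(unscat_vg, beam, quad, phantom, kernel)
    timings["sources"] <- proc.time()[["elapsed"]] - t0
    ph <- solve_photon_transport(unscat, tables, grid, quad,
                                 iterations = iterations, adaptive = mask,
                                 probes = probes)
    timings["photon_solve"] <- proc.time()[["elapsed"]] - t0
    eeg <- build_energy_grid("electron")
    exs <- build_electron_xs_tables(quad, eeg)
    qfix <- electron_fixed_source(ph$total, tables, grid$rho_e_abs, quad)
    el <- solve_electron_transport(qfix, exs, grid, quad,
                                   iterations = iterations, adaptive = mask,
                                   probes = probes)
    timings["electron_solve"] <- proc.time()[["elapsed"]] - t0
    dose <- dose_from_fluence(el$total, eeg, phantom, "electron")
    out <- list(dose = dose, fluence = el$total, photon_fluence = ph$total,
                trace = list(photon = ph$trace, electron = el$trace))
  } else {
    eg <- build_energy_grid("proton")
    xs <- build_proton_xs_tables(quad, eg)
    if (is.null(beam$layers)) {
      beam$layers <- sobp_layer_weights(100, 200, 100)
    }
    unscat_vg <- proton_unscattered_fluence(beam, phantom, eg, xs)
    mask <- if (adaptive) build_adaptive_mask(unscat_vg, grid, "proton")
    if (!is.null(kernel)) {
      unscat_vg <- .apply_kernel_vg(unscat_vg, phantom, kernel)
    }
    timings["sources"] <- proc.time()[["elapsed"]] - t0
    S <- proton_stopping_power(eg$energy)
    pr <- solve_proton_groupwise(unscat_vg, beam, quad, grid, xs,
                                 iterations = iterations, adaptive = mask,
                                 probes = probes, S_dose = S)
    timings["proton_solve"] <- proc.time()[["elapsed"]] - t0
    dose <- .dose_from_scalar(pr$phi_scalar, S, phantom)
    out <- list(dose = dose, fluence = pr$phi_scalar,
                trace = list(proton = pr$trace))
  }
  timings["total"] <- proc.time()[["elapsed"]] - t0
  out$beam <- beam; out$phantom <- phantom; out$timings <- timings
  out
}

# phantom from a config list (CLI)
.phantom_from_config <- function(pc) {
  if (!is.null(pc$preset)) {
    phantom_preset(pc$preset,
                   voxel_mm = if (is.null(pc$voxel_mm)) 2.5 else pc$voxel_mm,
                   dims_mm = if (is.null(pc$dims_mm)) c(300, 300, 300)
                             else as.numeric(pc$dims_mm))
  } else {
    make_phantom(as.numeric(pc$dims_mm), as.numeric(pc$voxel_mm),
                 density = if (is.null(pc$density)) 1.0 else pc$density,
                 block = pc$block)
  }
}

.beam_from_config <- function(bc, particle) {
  args <- list(particle = particle)
  for (nm in c("gantry_deg", "couch_deg", "sad_mm", "ssd_mm", "field_mm",
               "source_sigma_mm", "iso_mm", "mu_prime", "lambda", "tau")) {
    if (!is.null(bc[[nm]])) args[[nm]] <- as.numeric(bc[[nm]])
  }
  beam <- do.call(beam_config, args)
  if (!is.null(bc$layers)) {
    beam$layers <- as.data.frame(bc$layers)
  } else if (!is.null(bc$sobp)) {
    beam$layers <- sobp_layer_weights(bc$sobp$R_min_mm, bc$sobp$R_max_mm,
                                      if (is.null(bc$sobp$n_layers)) 100
                                      else bc$sobp$n_layers)
  }
  beam
}

#' Command-line interface
#'
#' Subcommands: `calc` (LBTE dose for the configured beam), `analytic`
#' (analytic proton comparator curve), `compare` (both plus a
#' percent-of-local-dose difference curve), `converge` (per-iteration probe
#' traces), `quadrature-report` (ordinate table).  All outputs are
#' deterministic for identical configs; the config is echoed into the JSON
#' report for provenance.
#'
#' @param args Character vector of arguments, e.g.
#'   `c("calc", "--config", "cfg.json", "--out", "outdir")`.
#' @return Exit status (0 on success), invisibly.
#' @export
ordose_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1) {
    message("usage: ordose <calc|analytic|compare|converge|quadrature-report> [--config cfg.json] [--out dir] [--iterations n] [--quadrature standard|fine] [--adaptive] [--kernel file.csv]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- .parse_cli_opts(args[-1])
  if (cmd == "quadrature-report") {
    q <- if (identical(opt$quadrature, "fine")) {
      build_fine_angular_quadrature()
    } else build_standard_angular_quadrature()
    print(q)
    print(q$ordinates, digits = 6)
    return(invisible(0L))
  }
  if (is.null(opt$config)) { message("missing --config"); return(invisible(1L)) }
  cfg <- tryCatch(read_config_json(opt$config), error = function(e) {
    message("config error: ", conditionMessage(e)); NULL
  })
  if (is.null(cfg)) return(invisible(1L))
  out_dir <- if (is.null(opt$out)) "." else opt$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  phantom <- .phantom_from_config(cfg$phantom)
  beam <- .beam_from_config(cfg$beam, cfg$particle)
  iters <- if (!is.null(opt$iterations)) as.integer(opt$iterations) else cfg$iterations
  quadname <- if (!is.null(opt$quadrature)) opt$quadrature else cfg$quadrature
  kernel <- if (!is.null(opt$kernel)) read_kernel_csv(opt$kernel)
  adaptive <- isTRUE(opt$adaptive) || cfg$adaptive

  report <- list(command = cmd, config = cfg, iterations = iters,
                 quadrature = quadname, adaptive = adaptive)
  if (cmd %in% c("calc", "compare", "converge")) {
    probes <- NULL
    if (cmd == "converge") {
      ctr <- round(phantom$dims / 2); ctr <- pmax(ctr, 1)
      probes <- (ctr[3] - 1) * phantom$dims[1] * phantom$dims[2] +
        (ctr[2] - 1) * phantom$dims[1] + ctr[1]
    }
    res <- calc_dose(phantom, beam, quadname, iterations = iters,
                     adaptive = adaptive, kernel = kernel, probes = probes)
    write_mhd(res$dose, file.path(out_dir, "dose.mhd"))
    curves <- extract_curves(res$dose, beam, phantom)
    write_curves_csv(curves$depth, file.path(out_dir, "depth_dose.csv"))
    write_curves_csv(curves$profile, file.path(out_dir, "profile.csv"))
    report$timings <- as.list(res$timings)
    if (cmd == "converge") {
      for (nm in names(res$trace)) {
        tr <- res$trace[[nm]]
        if (is.null(tr)) next
        df <- data.frame(iteration = seq_len(nrow(tr)), probe = tr[, 1])
        df$relative_change <- c(NA, abs(diff(df$probe)) /
                                     pmax(df$probe[-1], .Machine$double.eps))
        utils::write.csv(df, file.path(out_dir,
                                       paste0("converge_", nm, ".csv")),
                         row.names = FALSE)
      }
    }
  }
  if (cmd %in% c("analytic", "compare") && cfg$particle == "proton") {
    depth <- seq(0.5 * phantom$spacing[3], phantom$extent_mm[3] -
                   0.5 * phantom$spacing[3], by = phantom$spacing[3])
    lay <- if (!is.null(beam$layers)) beam$layers else
      sobp_layer_weights(100, 200, 100)
    an <- analytic_sobp(lay, depth, sad_mm = beam$sad_mm,
                        ssd_mm = beam$ssd_mm)
    write_curves_csv(an, file.path(out_dir, "analytic_depth_dose.csv"))
    if (cmd == "compare") {
      dd <- utils::read.csv(file.path(out_dir, "depth_dose.csv"))
      np <- normalize_pair(dd$dose, an$dose)
      diff <- percent_local_difference(np$lbte, np$comparator)
      utils::write.csv(data.frame(depth_mm = dd$depth_mm, lbte = np$lbte,
                                  analytic = np$comparator, diff_pct = diff),
                       file.path(out_dir, "compare.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(0L)
}

.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--adaptive") { opt$adaptive <- TRUE; i <- i + 1; next }
    if (a == "--no-adaptive") { opt$adaptive <- FALSE; i <- i + 1; next }
    if (startsWith(a, "--")) {
      opt[[substring(a, 3)]] <- args[i + 1]
      i <- i + 2
    } else i <- i + 1
  }
  opt
}
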