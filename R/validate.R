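#' Build a phantom scenario from a configuration
#'
#' @param name `"divergent"`, `"poiseuille"` or `"tofts"`.
#' @param cfg A configuration list (see [default_config()]).
#' @return A `flow_scenario` or `tofts_scenario`.
#' @export
build_scenario <- function(name, cfg = default_config()) {
  name <- match.arg(name, c("divergent", "poiseuille", "tofts"))
  g <- cfg$grid
  sc <- cfg$scenarios[[name]]
  if (name == "tofts") {
    grid <- lcfr_grid(g$nx, g$ny, g$dx, g$dy, dt = sc$dt,
                      n_steps = sc$n_frames - 1L)
    times <- (seq_len(sc$n_frames) - 1L) * sc$dt
    vif <- gamma_variate_vif(times, t0 = sc$vif$t0, alpha = sc$vif$alpha,
                             beta = sc$vif$beta, recirc = sc$vif$recirc)
    return(make_tofts_scenario(grid, ktrans = sc$ktrans, ve = sc$ve,
                               vp = sc$vp, vif = vif, dt = sc$dt))
  }
  grid <- lcfr_grid(g$nx, g$ny, g$dx, g$dy, g$dt, g$n_steps, g$save_stride)
  if (name == "divergent")
    make_divergent_field(grid, D = sc$D, speed = sc$speed,
                         bolus_radius = sc$bolus_radius)
  else
    make_poiseuille_field(grid, D = sc$D, u_max = sc$u_max,
                          half_width = sc$half_width,
                          bolus_radius = sc$bolus_radius)
}

#' Simulate a named phantom scenario with its ground truth
#'
#' @param name Scenario name (see [build_scenario()]).
#' @param cfg Configuration list.
#' @return A list: `conc` ([conc_image()]), `truth` (named list of ground-truth
#'   maps for [summarize_recovery()]), `scenario`, and `vif` (Tofts only).
#' @export
simulate_scenario <- function(name, cfg = default_config()) {
  sc <- build_scenario(name, cfg)
  z <- cfg$grid$z_slices
  if (inherits(sc, "tofts_scenario")) {
    conc <- simulate_extended_tofts(sc, z_slices = z)
    truth <- list(ktrans = sc$ktrans_map, vp = sc$vp,
                  efflux = sc$ktrans_map / sc$ve)
    list(conc = conc, truth = truth, scenario = sc, vif = sc$vif)
  } else {
    conc <- simulate_advection_diffusion(sc, z_slices = z)
    truth <- list(speed = scenario_speed(sc), u_x = sc$ux, u_y = sc$uy,
                  D_x = matrix(sc$D, nrow(sc$ux), ncol(sc$ux)),
                  D_y = matrix(sc$D, nrow(sc$ux), ncol(sc$ux)))
    list(conc = conc, truth = truth, scenario = sc, vif = NULL)
  }
}

#' One simulate-noise-fit-summarize pass on a phantom
#'
#' Adds one noise instantiation to a simulated scenario (instantiation `i`
#' uses seed `seed + i - 1`), runs the weak-form recovery with the
#' configuration's basis settings, and scores it against the scenario's
#' ground truth over the enhancing, Gibbs-trimmed analysis mask.
#'
#' @param sim A [simulate_scenario()] result.
#' @param cfg Configuration list (see [default_config()]).
#' @param noise_strength Noise fraction of the global signal maximum.
#' @param seed Base seed.
#' @param instantiation Noise instantiation index (1-based).
#' @return A list with `fit` (an `lcfr_fit`), `metrics` (tibble from
#'   [summarize_recovery()]) and `mask`.
#' @export
phantom_recovery <- function(sim, cfg, noise_strength, seed,
                             instantiation = 1L) {
  noisy <- add_noise(sim$conc, noise_spec(noise_strength, seed),
                     instantiation = instantiation)
  b <- cfg$basis
  dm <- dim(noisy$data)
  support <- c(min(b$spatial_half_width, (dm[1] - 3L) %/% 2L),
               min(b$spatial_half_width, (dm[2] - 3L) %/% 2L),
               max(1L, min(b$spatial_half_width, (dm[3] - 3L) %/% 2L)),
               min(b$temporal_half_width, (dm[4] - 1L) %/% 2L))
  fit <- recover_transport(noisy, vif = sim$vif, support = support,
                           degrees = b$degrees, trim = cfg$fit$trim,
                           rcond_tol = cfg$fit$rcond_tol, ridge = cfg$fit$ridge)
  mask <- mask_enhancing(sim$conc, cfg$fit$enhance_frac)
  metrics <- summarize_recovery(fit$physical, sim$truth, mask = mask)
  list(fit = fit, metrics = metrics, mask = mask)
}

#' Noise-robustness validation sweep
#'
#' Reruns the full simulate -> add-noise -> fit -> summarize chain for each
#' configured scenario, noise level, and noise instantiation (instantiation
#' `i` uses seed `base_seed + i - 1`), mirroring the in silico convergence
#' analysis: parameter error as a function of the noise fraction.
#'
#' @param cfg A configuration list (see [default_config()]).
#' @param scenarios Scenario names to run.
#' @param write Write CSV tables and convergence plots to `cfg$output_dir`.
#' @return An object of class `experiment_report`: a per-run metrics tibble
#'   (`runs`), a per-level median summary (`convergence`), and provenance
#'   (config hash, seed, package version).
#' @export
run_validation_suite <- function(cfg = default_config(),
                                 scenarios = c("divergent", "poiseuille", "tofts"),
                                 write = FALSE) {
  runs <- list()
  for (scen in scenarios) {
    sim <- simulate_scenario(scen, cfg)
    for (lvl in cfg$noise$levels) {
      for (i in seq_len(cfg$noise$n_instantiations)) {
        res <- phantom_recovery(sim, cfg, lvl, cfg$noise$base_seed,
                                 instantiation = i)
        runs[[length(runs) + 1L]] <- dplyr::mutate(
          res$metrics, scenario = scen, noise = lvl, instantiation = i,
          seed = cfg$noise$base_seed + i - 1L, .before = 1)
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  convergence <- runs |>
    dplyr::filter(!is.na(.data$median_rel_err)) |>
    dplyr::group_by(.data$scenario, .data$parameter, .data$noise) |>
    dplyr::summarise(
      median_rel_err = stats::median(.data$median_rel_err),
      rmse = stats::median(.data$rmse),
      n_runs = dplyr::n(), .groups = "drop")
  report <- structure(list(runs = runs, convergence = convergence,
                           config_hash = config_hash(cfg),
                           base_seed = cfg$noise$base_seed,
                           package_version = as.character(utils::packageVersion("lcfr"))),
                      class = "experiment_report")
  if (write) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(runs, file.path(cfg$output_dir, "runs.csv"),
                     row.names = FALSE)
    utils::write.csv(convergence,
                     file.path(cfg$output_dir, "convergence.csv"),
                     row.names = FALSE)
    p <- plot_convergence(report)
    ggplot2::ggsave(file.path(cfg$output_dir, "convergence.pdf"), p,
                    width = 7, height = 5)
  }
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> %d runs | config %s | seed %d | lcfr %s\n",
              nrow(x$runs) / max(1, length(unique(x$runs$parameter))),
              x$config_hash, x$base_seed, x$package_version))
  print(x$convergence, n = 20)
  invisible(x)
}
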