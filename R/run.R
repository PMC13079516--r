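#' Write a gain trajectory as CSV
#'
#' Columns `t,d_r,kappa,precision` with header; infinite precision (exact
#' veridical samples) is written as the literal `inf`.
#'
#' @param traj A [gain_trajectory()].
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  df$precision <- ifelse(is.finite(df$precision),
                         format(df$precision, digits = 15, trim = TRUE),
                         "inf")
  for (col in c("t", "d_r", "kappa")) {
    df[[col]] <- format(df[[col]], digits = 15, trim = TRUE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gain trajectory CSV
#' @param path Path to a CSV written by [write_trajectory_csv()] (or any CSV
#'   with `t` and `d_r` columns).
#' @return A [gain_trajectory()].
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("t", "d_r") %in% names(df))) {
    stop("trajectory CSV must have columns `t` and `d_r`", call. = FALSE)
  }
  gain_trajectory(as.numeric(df$t), as.numeric(df$d_r))
}

write_num_csv <- function(df, path) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) {
      df[[col]] <- format(df[[col]], digits = 15, trim = TRUE)
    }
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a pipeline subcommand
#'
#' Executes one of the package's reproducible pipelines and writes its
#' artifacts (CSV tables, JSON summaries) plus a run manifest to `out_dir`.
#' Every source of randomness derives from the config's master seed via
#' named child streams, so reruns with the same config and seed are
#' byte-identical (timestamps are confined to the manifest).
#'
#' Subcommands:
#' * `simulate`: integrate the restoring dynamics (optionally with a
#'   challenge) -> `trajectory.csv`;
#' * `compose`: weight table over durations and the composed total gain for
#'   the configured component gains -> `weights.csv`, `composition.json`;
#' * `scenario`: disorder-preset scenario -> per-component and total
#'   trajectory CSVs, `summary.json`;
#' * `tasks`: synthetic task dataset -> `trials.csv`;
#' * `fit`: fit the restoring dynamics to a trajectory CSV (the config's
#'   `fit.input`, else a trajectory simulated from the config) ->
#'   `fit.json`, `recovery.csv`;
#' * `report`: classify a scenario bundle (`report.input` directory) ->
#'   `report.json`.
#'
#' @param subcommand One of `"simulate"`, `"compose"`, `"scenario"`,
#'   `"tasks"`, `"fit"`, `"report"`.
#' @param config A `cdt_config` (see [cdt_config()], [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional master-seed override.
#' @return Invisibly, the paths of the written artifacts.
#' @export
cdt_run <- function(subcommand = c("simulate", "compose", "scenario", "tasks",
                                   "fit", "report"),
                    config = cdt_config(), out_dir, seed = NULL) {
  subcommand <- match.arg(subcommand)
  if (!inherits(config, "cdt_config")) config <- cdt_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- switch(subcommand,
    simulate = run_simulate(config, out_dir),
    compose = run_compose(config, out_dir),
    scenario = run_scenario(config, out_dir),
    tasks = run_tasks(config, out_dir),
    fit = run_fit(config, out_dir),
    report = run_report(config, out_dir))
  manifest <- write_manifest(config, out_dir, paths)
  invisible(c(paths, manifest))
}

run_simulate <- function(cfg, out_dir) {
  tr <- integrate_deviation(dynamics_params(cfg$dynamics$a, cfg$dynamics$b),
                            cfg$dynamics$d_r0, cfg$dynamics$dd_r0,
                            config_grid(cfg),
                            challenge = config_challenge(cfg))
  write_trajectory_csv(tr, file.path(out_dir, "trajectory.csv"))
}

run_compose <- function(cfg, out_dir) {
  profile <- config_profile(cfg)
  taus <- 10^seq(-2, 2, length.out = 200)
  wtab <- weights_at(taus, profile)
  p1 <- write_num_csv(wtab, file.path(out_dir, "weights.csv"))
  gains <- do.call(component_gains, cfg$gains)
  spec <- config_comparator(cfg)
  kappa <- total_gain_multiplicative(gains, tau = cfg$tau, profile = profile,
                                     spec = spec)
  p2 <- file.path(out_dir, "composition.json")
  jsonlite::write_json(list(tau = cfg$tau, kappa_total = kappa,
                            ln_kappa_total = log(kappa),
                            crossover_s = weight_crossover(profile)),
                       p2, auto_unbox = TRUE, digits = NA)
  c(p1, p2)
}

run_scenario <- function(cfg, out_dir) {
  prst <- if (cfg$preset$name == "null") {
    null_preset(seed = child_seed(cfg$seed, "scenario"))
  } else {
    preset(cfg$preset$name, delta = cfg$preset$delta,
           instability_sd = cfg$preset$instability_sd,
           seed = child_seed(cfg$seed, "scenario"))
  }
  sc <- simulate_scenario(prst,
                          params = dynamics_params(cfg$dynamics$a,
                                                   cfg$dynamics$b),
                          challenge = config_challenge(cfg), tau = cfg$tau,
                          profile = config_profile(cfg),
                          spec = config_comparator(cfg),
                          t = config_grid(cfg))
  paths <- c(
    write_trajectory_csv(sc$total, file.path(out_dir, "total.csv")),
    write_trajectory_csv(sc$components$cbl, file.path(out_dir, "cbl.csv")),
    write_trajectory_csv(sc$components$bg, file.path(out_dir, "bg.csv")),
    write_trajectory_csv(sc$components$ctx, file.path(out_dir, "ctx.csv")))
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(preset = prst$name, tau = cfg$tau,
         distortion = sc$classification$distortion,
         precision_level = sc$classification$precision_level,
         mean_kappa = sc$summary$mean_kappa,
         mean_abs_d_r = sc$summary$mean_abs_d_r,
         damping_regime = sc$damping),
    sp, auto_unbox = TRUE, digits = NA)
  c(paths, sp)
}

run_tasks <- function(cfg, out_dir) {
  seed <- child_seed(cfg$seed, paste0("tasks-", cfg$tasks$task))
  regime <- if (cfg$preset$name == "null") {
    do.call(component_gains, cfg$gains)
    # constant gains: compose directly
    total_gain_multiplicative(do.call(component_gains, cfg$gains),
                              tau = cfg$tau, profile = config_profile(cfg),
                              spec = config_comparator(cfg))
  } else {
    preset(cfg$preset$name, delta = cfg$preset$delta,
           instability_sd = cfg$preset$instability_sd, seed = seed)
  }
  ds <- generate_task_dataset(cfg$tasks$task, regime = regime,
                              n_trials = cfg$tasks$n_trials, seed = seed,
                              durations = cfg$tasks$durations,
                              noise = cfg$tasks$noise,
                              profile = config_profile(cfg))
  ds$seed <- seed
  write_num_csv(as.data.frame(ds), file.path(out_dir, "trials.csv"))
}

run_fit <- function(cfg, out_dir) {
  tr <- if (!is.null(cfg$fit$input)) {
    read_trajectory_csv(cfg$fit$input)
  } else {
    solve_deviation_closed_form(
      dynamics_params(cfg$dynamics$a, cfg$dynamics$b),
      cfg$dynamics$d_r0, cfg$dynamics$dd_r0, config_grid(cfg))
  }
  bounds <- list(a = as.numeric(cfg$fit$bounds$a),
                 b = as.numeric(cfg$fit$bounds$b))
  fit <- fit_dynamics(tr$t, tr$d_r, bounds = bounds,
                      n_starts = cfg$fit$n_starts,
                      seed = child_seed(cfg$seed, "fit"))
  p1 <- file.path(out_dir, "fit.json")
  jsonlite::write_json(
    list(estimates = as.list(coef(fit)), sigma = fit$sigma,
         objective = fit$objective, converged = fit$converged,
         degenerate = fit$degenerate, regime = fit$regime,
         seed = fit$seed),
    p1, auto_unbox = TRUE, digits = NA)
  # small self-recovery table around the fitted (or configured) dynamics
  a0 <- cfg$dynamics$a
  b0 <- cfg$dynamics$b
  rec <- recovery_study(
    generator = function(s) {
      base <- solve_deviation_closed_form(dynamics_params(a0, b0), 0.5, 0,
                                          seq(0, 10, length.out = 60))
      noisy <- with_seed(s, base$d_r + stats::rnorm(60, 0, 0.01))
      list(t = base$t, d_r = noisy)
    },
    estimator = function(d) {
      coef(fit_dynamics(d$t, d$d_r, bounds = bounds, n_starts = 8,
                        seed = child_seed(cfg$seed, "fit-recovery")))[c("a", "b")]
    },
    true = c(a = a0, b = b0), n_replicates = 5,
    seeds = child_seed(cfg$seed, "fit-replicates") + 0:4)
  p2 <- write_num_csv(as.data.frame(rec), file.path(out_dir, "recovery.csv"))
  c(p1, p2)
}

run_report <- function(cfg, out_dir) {
  input <- cfg$report$input
  if (is.null(input) || !dir.exists(input)) {
    stop("`report.input` must name a scenario output directory", call. = FALSE)
  }
  total <- read_trajectory_csv(file.path(input, "total.csv"))
  comp_files <- file.path(input, c("cbl.csv", "bg.csv", "ctx.csv"))
  comps <- if (all(file.exists(comp_files))) {
    stats::setNames(lapply(comp_files, read_trajectory_csv),
                    c("cbl", "bg", "ctx"))
  } else {
    stats::setNames(rep(list(total), 3), c("cbl", "bg", "ctx"))
  }
  sc <- build_scenario(total, comps, null_preset(),
                       dynamics_params(cfg$dynamics$a, cfg$dynamics$b),
                       NULL, cfg$tau, config_profile(cfg),
                       config_comparator(cfg), total$t)
  p <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(input = input, distortion = sc$classification$distortion,
         precision_level = sc$classification$precision_level,
         mean_kappa = sc$summary$mean_kappa,
         mean_abs_d_r = sc$summary$mean_abs_d_r),
    p, auto_unbox = TRUE, digits = NA)
  p
}

write_manifest <- function(cfg, out_dir, paths) {
  paths <- paths[file.exists(paths)]
  sums <- as.list(tools::md5sum(paths))
  names(sums) <- basename(names(sums))
  mp <- file.path(out_dir, "run_manifest.json")
  tmp <- paste0(mp, ".tmp")
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("cdtime")),
         timestamp = format(Sys.time(), tz = "UTC"),
         config = unclass(cfg), checksums = sums),
    tmp, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  file.rename(tmp, mp)
  mp
}
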