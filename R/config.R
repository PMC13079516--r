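default_config <- function() {
  list(
    seed = 1L,
    tau = 2,
    dynamics = list(a = 1, b = 2, d_r0 = 0, dd_r0 = 0),
    grid = list(t_end = 30, dt = 0.05),
    challenge = NULL,
    weights = list(tau_cross = 1, slope = 4, ctx_center = 0, ctx_width = 0.5,
                   ctx_height = 0.6),
    comparator = list(form = "default", g = 0),
    gains = list(kappa_cbl = 1, kappa_bg = 1, kappa_ctx = 1),
    preset = list(name = "null", delta = 0.2, instability_sd = 0.5),
    tasks = list(task = "reproduction", n_trials = 100, durations = NULL,
                 noise = NULL),
    fit = list(input = NULL, bounds = list(a = c(0.05, 25), b = c(0.05, 25)),
               n_starts = 16),
    report = list(input = NULL)
  )
}

#' Build a validated run configuration
#'
#' Assembles the nested configuration driving [cdt_run()], filling every
#' unspecified key with its documented default and validating the result.
#' Blocks: `dynamics` (a, b, initial state), `grid` (t_end, dt),
#' `challenge`, `weights`, `comparator`, `gains`, `preset`, `tasks`, `fit`,
#' `report`, plus the master `seed` and the probed duration `tau`.
#'
#' @param ... Named blocks or scalar keys overriding the defaults; nested
#'   blocks are merged key-by-key.
#' @return A validated list of class `cdt_config`.
#' @examples
#' cfg <- cdt_config(dynamics = list(a = 2), seed = 7)
#' cfg$dynamics$b  # default 2
#' @export
cdt_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]])) {
    user <- user[[1]]
  }
  cfg <- merge_config(default_config(), user)
  validate_config(cfg)
  structure(cfg, class = c("cdt_config", "list"))
}

merge_config <- function(base, user) {
  if (length(user) == 0) return(base)
  bad <- setdiff(names(user), c(names(base), ""))
  if (length(bad)) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.null(user[[k]])) next   # null in a file means "use the default"
    if (is.list(base[[k]]) && is.list(user[[k]]) && k != "challenge" &&
        !is.null(names(user[[k]]))) {
      for (kk in names(user[[k]])) {
        if (!is.null(user[[k]][[kk]])) base[[k]][kk] <- list(user[[k]][[kk]])
      }
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  fail <- function(key, constraint) {
    stop(sprintf("invalid config: `%s` %s", key, constraint), call. = FALSE)
  }
  d <- cfg$dynamics
  if (!is.numeric(d$a) || d$a <= 0) fail("dynamics.a", "must be > 0")
  if (!is.numeric(d$b) || d$b <= 0) fail("dynamics.b", "must be > 0")
  if (!is.numeric(d$d_r0) || !is.finite(d$d_r0)) {
    fail("dynamics.d_r0", "must be finite")
  }
  if (!is.numeric(cfg$grid$t_end) || cfg$grid$t_end <= 0) {
    fail("grid.t_end", "must be > 0")
  }
  if (!is.numeric(cfg$grid$dt) || cfg$grid$dt <= 0 ||
      cfg$grid$dt > cfg$grid$t_end) {
    fail("grid.dt", "must be in (0, t_end]")
  }
  if (!is.null(cfg$challenge)) {
    ch <- cfg$challenge
    if (!is.null(ch$shape) &&
        !ch$shape %in% c("step", "ramp", "impulse")) {
      fail("challenge.shape", "must be step, ramp or impulse")
    }
  }
  w <- cfg$weights
  if (w$tau_cross <= 0) fail("weights.tau_cross", "must be > 0")
  if (w$slope <= 0) fail("weights.slope", "must be > 0")
  if (w$ctx_width <= 0) fail("weights.ctx_width", "must be > 0")
  if (w$ctx_height < 0) fail("weights.ctx_height", "must be >= 0")
  g <- cfg$comparator$g
  if (!is.numeric(g) || g < 0 || g > 1) {
    fail("comparator.g", "must be in [0, 1]")
  }
  for (k in names(cfg$gains)) {
    if (cfg$gains[[k]] <= 0) fail(paste0("gains.", k), "must be > 0")
  }
  if (!cfg$preset$name %in% c("null", names(disorder_table))) {
    fail("preset.name", paste("must be one of: null,",
                              paste(names(disorder_table), collapse = ", ")))
  }
  if (cfg$tau <= 0) fail("tau", "must be > 0")
  if (!is.numeric(cfg$seed) || !is.finite(cfg$seed)) {
    fail("seed", "must be an integer")
  }
  invisible(cfg)
}

#' Load a run configuration from JSON or YAML
#'
#' Reads a configuration file (JSON, or YAML as a convenience dialect,
#' chosen by extension), merges it over the defaults and validates it.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A validated `cdt_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # jsonlite reads c(lo, hi) bounds back as vectors already; ensure lists
  cdt_config(raw)
}

#' Save a run configuration as JSON
#' @param cfg A `cdt_config`.
#' @param path Output path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

config_grid <- function(cfg) seq(0, cfg$grid$t_end, by = cfg$grid$dt)

config_challenge <- function(cfg) {
  if (is.null(cfg$challenge)) return(NULL)
  ch <- cfg$challenge
  challenge_protocol(onset = ch$onset %||% 0, duration = ch$duration %||% 1,
                     amplitude = ch$amplitude %||% 0.5,
                     shape = ch$shape %||% "step")
}

config_profile <- function(cfg) do.call(weight_profile, cfg$weights)

config_comparator <- function(cfg) {
  comparator_spec(g = cfg$comparator$g, form = cfg$comparator$form)
}
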