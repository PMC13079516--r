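#' Simulate a disorder scenario
#'
#' Runs a disorder regime through the full model: the preset's per-system
#' gain series are composed sample-by-sample into an equilibrium total gain
#' (weights evaluated at the probed interval duration `tau`, comparator per
#' `spec`), and an optional challenge drives an additional deviation that
#' the restoring dynamics relax back to zero. Because the restoring law is
#' linear, the total deviation is the equilibrium deviation plus the
#' challenge response (zero initial conditions); with a neutral preset and
#' no challenge the total gain is identically 1.
#'
#' @param prst A [preset()] (or [null_preset()]).
#' @param params [dynamics_params()] of the restoring law.
#' @param challenge Optional [challenge_protocol()].
#' @param tau Interval duration probed, seconds (sets the system weights).
#' @param profile [weight_profile()].
#' @param spec [comparator_spec()].
#' @param t Time grid, seconds.
#' @return An object of class `cdt_scenario`: total and component
#'   [gain_trajectory()]s, the damping-regime label, classification (see
#'   [classify_regime()]), and summary statistics (mean gain, mean absolute
#'   deviation, mean finite precision).
#' @export
simulate_scenario <- function(prst, params = dynamics_params(1, 2),
                              challenge = NULL, tau = 2,
                              profile = weight_profile(),
                              spec = comparator_spec(),
                              t = seq(0, 30, by = 0.05)) {
  stopifnot(inherits(prst, "cdt_preset"))
  params <- as_dynamics(params)
  check_grid(t)
  logs <- preset_log_gain_series(prst, t)
  comps <- lapply(logs, function(lk) gain_trajectory(t, exp(lk) - 1))
  names(comps) <- c("cbl", "bg", "ctx")
  total_eq <- compose_trajectory(comps$cbl, comps$bg, comps$ctx, tau = tau,
                                 profile = profile, spec = spec)
  chal <- if (is.null(challenge)) {
    rep(0, length(t))
  } else {
    integrate_deviation(params, 0, 0, t, challenge = challenge)$d_r
  }
  total <- gain_trajectory(t, total_eq$d_r + chal, params = params)
  build_scenario(total, comps, prst, params, challenge, tau, profile, spec, t)
}

build_scenario <- function(total, comps, prst, params, challenge, tau,
                           profile, spec, t, damping = NULL) {
  if (is.null(damping)) damping <- damping_regime(params, warn = FALSE)
  res <- structure(
    list(total = total, components = comps, preset = prst, params = params,
         challenge = challenge, tau = tau, profile = profile, spec = spec,
         grid = t, damping = damping,
         summary = list(mean_kappa = mean(total$kappa),
                        mean_abs_d_r = mean(abs(total$d_r)),
                        mean_finite_P = {
                          fp <- total$precision[is.finite(total$precision)]
                          if (length(fp)) mean(fp) else Inf
                        })),
    class = "cdt_scenario")
  res$classification <- classify_regime(res)
  res
}

#' @export
print.cdt_scenario <- function(x, ...) {
  cat(sprintf("Scenario: preset '%s', tau = %g s, comparator g = %g\n",
              x$preset$name, x$tau, x$spec$g))
  cat(sprintf("  damping: %s; mean kappa = %.4f; mean |D_r| = %.4f\n",
              paste(x$damping, collapse = " -> "),
              x$summary$mean_kappa, x$summary$mean_abs_d_r))
  cat(sprintf("  classified: %s, precision %s\n",
              x$classification$distortion, x$classification$precision_level))
  invisible(x)
}

#' Classify the timing regime of a scenario
#'
#' Labels the total gain trajectory as dilated, compressed, unstable or
#' normal, plus a precision level:
#' * unstable: the deviation changes sign at least `min_sign_changes` times
#'   and exceeds `theta` in magnitude somewhere;
#' * dilated / compressed: the time-averaged deviation exceeds `+theta` /
#'   falls below `-theta`;
#' * normal otherwise.
#'
#' The precision level is structural for unstable regimes: "unstable" when
#' every component-gain trajectory is itself unstable (jitter in all three
#' systems), "low" when only some are — timing noise concentrated in a
#' subset of systems degrades precision without full desynchrony. For
#' stable regimes it is "low" when the summary precision `1 / mean(|D_r|)`
#' falls below `p_low`, else "normal".
#'
#' @param result A `cdt_scenario` from [simulate_scenario()].
#' @param theta Deviation threshold for dilation/compression (default 0.05).
#' @param min_sign_changes Sign-change count for instability (default 3).
#' @param p_low Summary-precision threshold separating low from normal
#'   precision (default 8).
#' @return A list with `distortion` and `precision_level`.
#' @export
classify_regime <- function(result, theta = 0.05, min_sign_changes = 3,
                            p_low = 8) {
  stopifnot(inherits(result, "cdt_scenario"))
  distortion <- classify_series(result$total$d_r, theta, min_sign_changes)
  comp_labels <- vapply(result$components, function(tr) {
    classify_series(tr$d_r, theta, min_sign_changes)
  }, character(1))
  summary_P <- 1 / mean(abs(result$total$d_r))
  precision_level <- if (distortion == "unstable") {
    if (all(comp_labels == "unstable")) "unstable" else "low"
  } else if (summary_P < p_low) {
    "low"
  } else {
    "normal"
  }
  list(distortion = distortion, precision_level = precision_level,
       component_distortion = comp_labels, summary_precision = summary_P)
}

classify_series <- function(d_r, theta, min_sign_changes) {
  s <- sign(d_r)
  s <- s[s != 0]
  changes <- if (length(s) > 1L) sum(diff(s) != 0) else 0L
  if (changes >= min_sign_changes && max(abs(d_r)) > theta) return("unstable")
  m <- mean(d_r)
  if (m > theta) "dilated" else if (m < -theta) "compressed" else "normal"
}

#' Intervention specification
#'
#' Interventions are parameter changes applied from an onset time onward —
#' raising the comparator gain, stiffening the restoring or damping
#' coefficient, or shifting one system's log-gain — mirroring how
#' neuromodulation is framed in the model (an adjustment of comparator gain
#' and synchrony, not a biophysical stimulation model).
#'
#' @param target One of `"comparator_gain"`, `"damping_b"`, `"restoring_a"`,
#'   `"component_kappa"`.
#' @param delta Signed change: on `g` for the comparator, additive on `a` or
#'   `b`, additive on `ln kappa` for a component.
#' @param system For `component_kappa`: `"cbl"`, `"bg"` or `"ctx"`.
#' @param onset Time the change takes effect, seconds (rounded to the
#'   nearest grid point of the scenario it is applied to).
#' @return An object of class `cdt_intervention`.
#' @export
intervention_spec <- function(target = c("comparator_gain", "damping_b",
                                         "restoring_a", "component_kappa"),
                              delta, system = NULL, onset = 0) {
  target <- match.arg(target)
  if (!is.finite(delta)) stop("`delta` must be finite", call. = FALSE)
  if (target == "component_kappa" &&
      (is.null(system) || !system %in% c("cbl", "bg", "ctx"))) {
    stop("`system` must be one of 'cbl', 'bg', 'ctx' for component_kappa",
         call. = FALSE)
  }
  if (!is.finite(onset) || onset < 0) stop("`onset` must be >= 0", call. = FALSE)
  structure(list(target = target, delta = delta, system = system,
                 onset = onset),
            class = "cdt_intervention")
}

#' Apply an intervention to a simulated scenario
#'
#' Re-simulates the scenario with the intervention's parameter change in
#' force from its onset: the comparator gain, dynamics coefficients, or a
#' component log-gain switch value at the grid point nearest the onset.
#' Post-change parameters must respect the model's bounds (`a, b > 0`,
#' `0 <= g <= 1`). A zero-delta intervention reproduces the original
#' trajectories exactly.
#'
#' @param result A `cdt_scenario`.
#' @param intervention An [intervention_spec()].
#' @return A new `cdt_scenario` with the intervention in force.
#' @export
apply_intervention <- function(result, intervention) {
  stopifnot(inherits(result, "cdt_scenario"),
            inherits(intervention, "cdt_intervention"))
  t <- result$grid
  onset <- t[which.min(abs(t - intervention$onset))]
  prst <- result$preset
  params <- result$params
  spec <- result$spec

  logs <- preset_log_gain_series(prst, t)
  if (intervention$target == "component_kappa") {
    logs[[intervention$system]] <- logs[[intervention$system]] +
      ifelse(t >= onset, intervention$delta, 0)
  }
  comps <- lapply(logs, function(lk) gain_trajectory(t, exp(lk) - 1))
  names(comps) <- c("cbl", "bg", "ctx")

  # comparator gain may differ before/after onset
  spec_post <- spec
  if (intervention$target == "comparator_gain") {
    g2 <- spec$g + intervention$delta
    if (!is.finite(g2) || g2 < 0 || g2 > 1) {
      stop(sprintf("intervention pushes comparator gain to %g, outside [0, 1]",
                   g2), call. = FALSE)
    }
    spec_post <- comparator_spec(g2, spec$form)
  }
  pre <- t < onset
  weights <- weights_at(result$tau, result$profile)
  kappa_eq <- vapply(seq_along(t), function(i) {
    total_gain_multiplicative(
      component_gains(comps$cbl$kappa[i], comps$bg$kappa[i],
                      comps$ctx$kappa[i]),
      weights = weights, spec = if (pre[i]) spec else spec_post)
  }, numeric(1))

  # dynamics coefficients may switch at onset; challenge response is
  # re-integrated with the piecewise-constant law
  a2 <- params$a + if (intervention$target == "restoring_a") {
    intervention$delta
  } else 0
  b2 <- params$b + if (intervention$target == "damping_b") {
    intervention$delta
  } else 0
  if (a2 <= 0 || b2 <= 0) {
    stop("intervention pushes a dynamics coefficient to <= 0", call. = FALSE)
  }
  params_post <- dynamics_params(a2, b2)
  afun <- function(tt) if (tt < onset) params$a else a2
  bfun <- function(tt) if (tt < onset) params$b else b2
  chal <- if (is.null(result$challenge)) {
    rep(0, length(t))
  } else {
    ch <- result$challenge
    u <- if (ch$shape == "impulse") {
      function(tt) 0
    } else {
      base <- challenge_forcing(ch, 1)   # unit-a forcing profile
      function(tt) afun(tt) * base(tt)
    }
    impulse <- if (ch$shape == "impulse") c(ch$onset, ch$amplitude) else NULL
    h_max <- min(0.005, 0.05 / sqrt(max(params$a, a2)))
    rk4_deviation(afun, bfun, u, 0, 0, t, h_max, impulse,
                  breaks = c(challenge_breaks(ch), onset))$d
  }
  total <- gain_trajectory(t, (kappa_eq - 1) + chal, params = params_post)
  damping <- unique(c(damping_regime(params, warn = FALSE),
                      damping_regime(params_post, warn = FALSE)))
  out <- build_scenario(total, comps, prst, params_post, result$challenge,
                        result$tau, result$profile, spec_post, t,
                        damping = damping)
  out$intervention <- intervention
  out
}
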