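#' Subjective duration of an objective interval
#'
#' Subjective time runs at a gain `kappa` relative to objective time: an
#' objective interval `dt` is experienced as `kappa * dt`. `kappa > 1` is
#' dilation (time feels longer), `kappa < 1` compression.
#'
#' @param kappa Subjective-time gain factor (dimensionless, > 0). Vectorised.
#' @param dt Objective interval, seconds (>= 0). Vectorised.
#' @return Subjective interval(s), seconds.
#' @examples
#' subjective_interval(1.5, 2)   # 3: dilated
#' subjective_interval(0.5, 2)   # 1: compressed
#' @export
subjective_interval <- function(kappa, dt) {
  check_gain(kappa)
  if (any(!is.finite(dt)) || any(dt < 0)) {
    stop("`dt` must be finite and >= 0", call. = FALSE)
  }
  kappa * dt
}

#' Subjective period of the internal clock
#'
#' The same gain relation applied to the period of a periodic clock signal:
#' the subjective period is `kappa * tau_p`.
#'
#' @inheritParams subjective_interval
#' @param tau_p Objective clock period, seconds (> 0).
#' @return Subjective period(s), seconds.
#' @export
subjective_period <- function(kappa, tau_p) {
  check_gain(kappa)
  check_positive(tau_p, "tau_p")
  kappa * tau_p
}

#' Absolute deviation of the clock period
#'
#' Difference between subjective and objective clock period, in seconds.
#'
#' @param tau_s Subjective period, seconds (> 0).
#' @param tau_p Objective period, seconds (> 0).
#' @return `tau_s - tau_p`, seconds.
#' @export
absolute_deviation <- function(tau_s, tau_p) {
  check_positive(tau_s, "tau_s")
  check_positive(tau_p, "tau_p")
  tau_s - tau_p
}

#' Relative deviation of subjective time
#'
#' The normalised mismatch between subjective and objective clock periods,
#' `D_r = kappa - 1`. Zero means veridical timing.
#'
#' @inheritParams subjective_interval
#' @return Relative deviation(s), dimensionless.
#' @export
relative_deviation <- function(kappa) {
  check_gain(kappa)
  kappa - 1
}

#' Timing precision
#'
#' Precision is the reciprocal of the absolute relative deviation,
#' `P = 1 / |D_r|`. It diverges at veridical timing (`D_r = 0`); the exact
#' form returns `Inf` there. For plotting and fitting, a regularised variant
#' `1 / max(|D_r|, eps)` is available via `regularize`.
#'
#' @param d_r Relative deviation(s), finite.
#' @param regularize If `TRUE`, floor `|d_r|` at `eps` instead of returning
#'   `Inf`.
#' @param eps Regularisation floor (default `1e-6`).
#' @return Precision value(s); `Inf` where `d_r == 0` unless regularised.
#' @export
precision <- function(d_r, regularize = FALSE, eps = 1e-6) {
  if (any(!is.finite(d_r))) stop("`d_r` must be finite", call. = FALSE)
  if (regularize) 1 / pmax(abs(d_r), eps) else 1 / abs(d_r)
}

#' Restoring-dynamics parameters
#'
#' The relative deviation relaxes to zero under a second-order linear law
#' `D_r'' = -a D_r - b D_r'`: a restoring force proportional to the deviation
#' plus a damping force proportional to its rate of change. Both coefficients
#' must be positive. Only their ratios matter under a rescaling of time; the
#' package fixes time in seconds, so `a` is 1/s^2 and `b` is 1/s.
#'
#' @param a Restoring coefficient, 1/s^2 (> 0).
#' @param b Damping coefficient, 1/s (> 0).
#' @return An object of class `cdt_dynamics` (list with `a`, `b`).
#' @examples
#' dynamics_params(1, 2)  # critically damped
#' @export
dynamics_params <- function(a, b) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0) {
    stop("restoring coefficient `a` must be a single finite value > 0",
         call. = FALSE)
  }
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0) {
    stop("damping coefficient `b` must be a single finite value > 0",
         call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b)),
            class = "cdt_dynamics")
}

#' @export
print.cdt_dynamics <- function(x, ...) {
  cat(sprintf("Restoring dynamics: a = %g (1/s^2), b = %g (1/s) [%s]\n",
              x$a, x$b, damping_regime(x, warn = FALSE)))
  invisible(x)
}

#' Damping regime of the restoring dynamics
#'
#' Classifies the dynamics by the sign of the discriminant `b^2 - 4a`.
#' The model's rationale calls for smooth, non-oscillatory restoration, so
#' an underdamped parameterisation (`b^2 < 4a`) is allowed but triggers a
#' warning.
#'
#' @param params A [dynamics_params()] object.
#' @param warn Emit a warning when underdamped (default `TRUE`).
#' @return One of `"underdamped"`, `"critical"`, `"overdamped"`.
#' @export
damping_regime <- function(params, warn = TRUE) {
  params <- as_dynamics(params)
  disc <- params$b^2 - 4 * params$a
  if (abs(disc) <= 1e-12 * max(1, params$b^2)) {
    "critical"
  } else if (disc > 0) {
    "overdamped"
  } else {
    if (warn) {
      warning("underdamped dynamics (b^2 < 4a): restoration will oscillate",
              call. = FALSE)
    }
    "underdamped"
  }
}

## ---- internal validators ----

check_gain <- function(kappa) {
  if (any(!is.finite(kappa)) || any(kappa <= 0)) {
    stop("gain `kappa` must be finite and > 0", call. = FALSE)
  }
  invisible(kappa)
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}

as_dynamics <- function(params) {
  if (inherits(params, "cdt_dynamics")) return(params)
  if (is.list(params) && all(c("a", "b") %in% names(params))) {
    return(dynamics_params(params$a, params$b))
  }
  stop("`params` must be a `cdt_dynamics` object (see dynamics_params())",
       call. = FALSE)
}

check_grid <- function(t) {
  if (!is.numeric(t) || length(t) < 1L || any(!is.finite(t))) {
    stop("time grid must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (t[1] < 0) stop("time grid must start at t >= 0", call. = FALSE)
  if (length(t) > 1L && any(diff(t) <= 0)) {
    stop("time grid must be strictly increasing", call. = FALSE)
  }
  invisible(t)
}
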