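#' Gain trajectory container
#'
#' A sampled trajectory of the subjective-time gain on a time grid, holding
#' `t`, the relative deviation `d_r`, the gain `kappa = 1 + d_r`, and the
#' precision `1/|d_r|` (`Inf` at veridical samples). Built by the solvers;
#' can also be assembled directly from a deviation series.
#'
#' @param t Strictly increasing sample times, seconds (first >= 0).
#' @param d_r Relative deviation at each sample.
#' @param params Optional [dynamics_params()] used to produce the trajectory.
#' @return A data frame of class `cdt_trajectory` with columns
#'   `t`, `d_r`, `kappa`, `precision`.
#' @export
gain_trajectory <- function(t, d_r, params = NULL) {
  check_grid(t)
  if (length(d_r) != length(t)) {
    stop("`d_r` must have one value per grid point", call. = FALSE)
  }
  kappa <- 1 + d_r
  if (any(kappa <= 0)) {
    warning("trajectory crosses kappa <= 0 (D_r <= -1): ",
            "a nonpositive subjective-time rate is outside the model's domain",
            call. = FALSE)
  }
  out <- data.frame(t = t, d_r = d_r, kappa = kappa,
                    precision = precision(d_r))
  attr(out, "params") <- params
  class(out) <- c("cdt_trajectory", "data.frame")
  out
}

#' @export
print.cdt_trajectory <- function(x, ...) {
  cat(sprintf("Gain trajectory: %d samples on t = [%g, %g] s\n",
              nrow(x), x$t[1], x$t[nrow(x)]))
  cat(sprintf("  mean kappa %.4f, mean |D_r| %.4f, final D_r %.3e\n",
              mean(x$kappa), mean(abs(x$d_r)), x$d_r[nrow(x)]))
  p <- attr(x, "params")
  if (!is.null(p)) {
    cat(sprintf("  dynamics: a = %g, b = %g (%s)\n", p$a, p$b,
                damping_regime(p, warn = FALSE)))
  }
  invisible(x)
}

#' @export
plot.cdt_trajectory <- function(x, which = c("d_r", "kappa"), ...) {
  which <- match.arg(which)
  ylab <- if (which == "d_r") "relative deviation D_r(t)" else
    expression(kappa(t))
  graphics::plot(x$t, x[[which]], type = "l", xlab = "time (s)", ylab = ylab,
                 ...)
  graphics::abline(h = if (which == "d_r") 0 else 1, lty = 3)
  invisible(x)
}

#' Challenge protocol
#'
#' An external perturbation epoch that drives the deviation away from zero,
#' after which the restoring dynamics relax it back. The perturbation enters
#' the deviation equation as an additive forcing `u(t)`:
#' * `step`: `u = a * amplitude` on `[onset, onset + duration]`, so
#'   `amplitude` is the steady-state deviation the challenge would hold the
#'   system at if sustained;
#' * `ramp`: `u` rises linearly from 0 to `a * amplitude` over the epoch;
#' * `impulse`: an instantaneous velocity increment of `amplitude` (1/s) at
#'   `onset` (`duration` is ignored).
#'
#' With no challenge the dynamics reduce exactly to the homogeneous
#' restoring law.
#'
#' @param onset Challenge onset, seconds (>= 0).
#' @param duration Epoch length, seconds (>= 0).
#' @param amplitude Target deviation (dimensionless), or velocity kick for
#'   `impulse`.
#' @param shape `"step"`, `"ramp"` or `"impulse"`.
#' @return An object of class `cdt_challenge`.
#' @export
challenge_protocol <- function(onset = 0, duration = 1, amplitude = 0.5,
                               shape = c("step", "ramp", "impulse")) {
  shape <- match.arg(shape)
  if (!is.finite(onset) || onset < 0) stop("`onset` must be >= 0", call. = FALSE)
  if (!is.finite(duration) || duration < 0) {
    stop("`duration` must be >= 0", call. = FALSE)
  }
  if (!is.finite(amplitude)) stop("`amplitude` must be finite", call. = FALSE)
  structure(list(onset = onset, duration = duration, amplitude = amplitude,
                 shape = shape),
            class = "cdt_challenge")
}

## forcing u(t) for a challenge (0 when challenge is NULL); impulse handled
## separately as a state jump
challenge_forcing <- function(challenge, a) {
  if (is.null(challenge)) return(function(t) 0)
  stopifnot(inherits(challenge, "cdt_challenge"))
  on <- challenge$onset
  off <- challenge$onset + challenge$duration
  amp <- challenge$amplitude
  # half-open [onset, onset + duration): the integrator takes left limits at
  # span edges, so the discontinuities land exactly
  switch(challenge$shape,
    step = function(t) if (t >= on && t < off) a * amp else 0,
    ramp = function(t) {
      if (t < on || t >= off || off == on) return(0)
      a * amp * (t - on) / (off - on)
    },
    impulse = function(t) 0
  )
}

#' Closed-form solution of the deviation dynamics
#'
#' Exact analytic solution of `D_r'' = -a D_r - b D_r'` for initial deviation
#' `d_r0` and initial rate `dd_r0`, using the branch selected by the
#' discriminant `b^2 - 4a`: two real exponentials (overdamped), the
#' critically damped `(c1 + c2 t) e^{-bt/2}` form, or a damped cosine
#' (underdamped). For all `a, b > 0` the solution decays to zero — the
#' regulatory dynamics restore veridical timing.
#'
#' @param params A [dynamics_params()] object.
#' @param d_r0 Initial relative deviation.
#' @param dd_r0 Initial rate of change, 1/s.
#' @param t Time grid (strictly increasing, first >= 0).
#' @return A [gain_trajectory()].
#' @examples
#' tr <- solve_deviation_closed_form(dynamics_params(1, 2), 1, 0, seq(0, 10, 0.1))
#' tr$d_r[tr$t == 1]  # (1 + 1) * exp(-1)
#' @export
solve_deviation_closed_form <- function(params, d_r0, dd_r0, t) {
  params <- as_dynamics(params)
  check_grid(t)
  gain_trajectory(t, deviation_closed_form(params$a, params$b, d_r0, dd_r0, t),
                  params = params)
}

## vectorised analytic evaluation (internal; also the integrator oracle)
deviation_closed_form <- function(a, b, d0, v0, t) {
  disc <- b^2 - 4 * a
  if (abs(disc) <= 1e-12 * max(1, b^2)) {
    r <- -b / 2
    c2 <- v0 - r * d0
    (d0 + c2 * t) * exp(r * t)
  } else if (disc > 0) {
    s <- sqrt(disc)
    r1 <- (-b + s) / 2
    r2 <- (-b - s) / 2
    c1 <- (v0 - r2 * d0) / (r1 - r2)
    c2 <- d0 - c1
    c1 * exp(r1 * t) + c2 * exp(r2 * t)
  } else {
    alpha <- b / 2
    omega <- sqrt(-disc) / 2
    c2 <- (v0 + alpha * d0) / omega
    exp(-alpha * t) * (d0 * cos(omega * t) + c2 * sin(omega * t))
  }
}

#' Numerical integration of the deviation dynamics
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' `D_r'' = -a D_r - b D_r' + u(t)`, where `u(t)` is the forcing of an
#' optional [challenge_protocol()] (with `challenge = NULL` the equation is
#' the homogeneous restoring law and the result matches
#' [solve_deviation_closed_form()] to high accuracy). The system is linear
#' and non-stiff at intended parameters; a fixed step
#' (`<= min(0.005, 0.05/sqrt(a))` s) keeps runs bit-reproducible.
#'
#' @inheritParams solve_deviation_closed_form
#' @param challenge Optional [challenge_protocol()] forcing.
#' @param h_max Upper bound on the internal step, seconds. The default
#'   adapts to the restoring stiffness.
#' @return A [gain_trajectory()].
#' @export
integrate_deviation <- function(params, d_r0, dd_r0, t, challenge = NULL,
                                h_max = NULL) {
  params <- as_dynamics(params)
  check_grid(t)
  a <- params$a
  b <- params$b
  if (is.null(h_max)) h_max <- min(0.005, 0.05 / sqrt(a))
  if (!is.finite(h_max) || h_max <= 0) {
    stop("integration error: step bound must be > 0", call. = FALSE)
  }
  u <- challenge_forcing(challenge, a)
  impulse <- if (!is.null(challenge) && challenge$shape == "impulse") {
    c(challenge$onset, challenge$amplitude)
  } else NULL
  sol <- rk4_deviation(function(tt) a, function(tt) b, u, d_r0, dd_r0, t,
                       h_max, impulse, breaks = challenge_breaks(challenge))
  gain_trajectory(t, sol$d, params = params)
}

## discontinuity times of a challenge's forcing
challenge_breaks <- function(challenge) {
  if (is.null(challenge) || challenge$shape == "impulse") return(numeric(0))
  c(challenge$onset, challenge$onset + challenge$duration)
}

## fixed-step RK4 for D'' = -a(t) D - b(t) D' + u(t) with an optional
## instantaneous velocity jump (impulse = c(time, amount)); a(t), b(t) may be
## piecewise constant. Substep spans are split at grid points, at forcing
## discontinuities (`breaks`) and at the impulse, and stage evaluations at a
## span's right endpoint use the left limit of u, so RK4 never straddles a
## jump. Returns d and dd at grid points.
rk4_deviation <- function(afun, bfun, u, d0, v0, t, h_max, impulse = NULL,
                          breaks = numeric(0)) {
  imp_t <- if (is.null(impulse)) NA_real_ else impulse[1]
  y <- c(d0, v0)
  imp_done <- FALSE
  if (!is.na(imp_t) && imp_t <= t[1]) {
    y[2] <- y[2] + impulse[2]
    imp_done <- TRUE
  }
  n <- length(t)
  d <- numeric(n)
  v <- numeric(n)
  d[1] <- y[1]
  v[1] <- y[2]
  cuts <- sort(unique(c(breaks, if (!imp_done && !is.na(imp_t)) imp_t)))
  if (n > 1L) {
    for (i in 2:n) {
      t0 <- t[i - 1]
      t1 <- t[i]
      edges <- sort(unique(c(t0, cuts[cuts > t0 & cuts < t1], t1)))
      for (j in seq_len(length(edges) - 1L)) {
        sp1 <- edges[j]
        sp2 <- edges[j + 1L]
        len <- sp2 - sp1
        if (len > 0) {
          # left-limit forcing at the span's right endpoint
          uu <- function(tt) u(if (tt >= sp2) sp2 - 1e-9 * max(1, abs(sp2))
                               else tt)
          deriv <- function(tt, y) {
            c(y[2], -afun(tt) * y[1] - bfun(tt) * y[2] + uu(tt))
          }
          n_sub <- max(1L, ceiling(len / h_max))
          h <- len / n_sub
          tt <- sp1
          for (k in seq_len(n_sub)) {
            k1 <- deriv(tt, y)
            k2 <- deriv(tt + h / 2, y + h / 2 * k1)
            k3 <- deriv(tt + h / 2, y + h / 2 * k2)
            k4 <- deriv(tt + h, y + h * k3)
            y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
            tt <- tt + h
          }
        }
        if (!imp_done && !is.na(imp_t) && sp2 >= imp_t) {
          y[2] <- y[2] + impulse[2]
          imp_done <- TRUE
        }
      }
      if (any(!is.finite(y))) {
        stop(sprintf("integration error at t = %g: state not finite", t1),
             call. = FALSE)
      }
      d[i] <- y[1]
      v[i] <- y[2]
    }
  }
  list(d = d, dd = v)
}

#' Dynamics of the gain factor
#'
#' The gain obeys `kappa'' = -a (kappa - 1) - b kappa'`, the deviation law
#' shifted by the change of variables `kappa = 1 + D_r`. Solved exactly via
#' [solve_deviation_closed_form()].
#'
#' @inheritParams solve_deviation_closed_form
#' @param kappa0 Initial gain (> 0).
#' @param dkappa0 Initial rate of change of the gain, 1/s.
#' @return A [gain_trajectory()].
#' @export
gain_dynamics <- function(params, kappa0, dkappa0, t) {
  check_gain(kappa0)
  solve_deviation_closed_form(params, kappa0 - 1, dkappa0, t)
}
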