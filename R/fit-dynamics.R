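#' Fit the restoring dynamics to a sampled deviation trajectory
#'
#' Least-squares fit of the closed-form solution of
#' `D_r'' = -a D_r - b D_r'` to noisy deviation samples, estimating the
#' restoring coefficient `a`, damping coefficient `b`, the initial state
#' `(D_r0, dD_r0)` and the observation noise sd. For fixed `(a, b)` the
#' solution is linear in the two branch basis coefficients, so the initial
#' state is profiled out by linear least squares and the optimisation runs
#' over `(ln a, ln b)` only, with Latin-hypercube multi-start over the
#' bounds (the likelihood has branch-dependent local optima). All three
#' damping branches are handled.
#'
#' Trajectories that never leave zero (max `|D_r|` below `1e-6`) solve the
#' dynamics for every `(a, b)` and are flagged degenerate instead of
#' returning arbitrary estimates.
#'
#' @param t Sample times, seconds (>= 8 samples).
#' @param d_r Observed relative deviation at each sample.
#' @param bounds List with elements `a` and `b`, each a positive
#'   `c(lower, upper)` search range.
#' @param n_starts Number of Latin-hypercube starts (default 16).
#' @param seed Seed for the start design.
#' @return An object of class `cdt_fit` with components `coefficients`
#'   (`a`, `b`, `d_r0`, `dd_r0`), `sigma` (noise sd), `vcov`, `se`,
#'   `objective` (residual sum of squares), `converged`, `degenerate`,
#'   `regime`, and the data. Methods: `print`, `summary`, `coef`, `vcov`,
#'   `predict`, `fitted`, `residuals`, `simulate`, `plot`.
#' @examples
#' tr <- solve_deviation_closed_form(dynamics_params(1, 2), 1, 0, seq(0, 10, 0.2))
#' fit <- fit_dynamics(tr$t, tr$d_r)
#' coef(fit)
#' @export
fit_dynamics <- function(t, d_r, bounds = list(a = c(0.05, 25),
                                               b = c(0.05, 25)),
                         n_starts = 16, seed = 1L) {
  check_grid(t)
  if (length(d_r) != length(t)) {
    stop("`d_r` must have one value per sample time", call. = FALSE)
  }
  if (length(t) < 8L) stop("need at least 8 samples", call. = FALSE)
  if (any(unlist(bounds) <= 0)) stop("bounds must be positive", call. = FALSE)

  if (max(abs(d_r)) < 1e-6) {
    return(new_cdt_fit(
      coefficients = c(a = NA_real_, b = NA_real_, d_r0 = 0, dd_r0 = 0),
      sigma = stats::sd(d_r), vcov = NULL, objective = sum(d_r^2),
      converged = FALSE, degenerate = TRUE, regime = NA_character_,
      t = t, d_r = d_r, fitted = rep(0, length(t)), seed = seed))
  }

  lb <- log(c(bounds$a[1], bounds$b[1]))
  ub <- log(c(bounds$a[2], bounds$b[2]))
  obj <- function(p) profile_rss(exp(p[1]), exp(p[2]), t, d_r)$rss

  starts <- with_seed(seed, lhs::randomLHS(n_starts, 2))
  starts <- sweep(sweep(starts, 2, ub - lb, "*"), 2, lb, "+")
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B", lower = lb,
                   upper = ub, control = list(factr = 10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    any_conv <- any_conv || res$convergence == 0
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(new_cdt_fit(
      coefficients = c(a = NA_real_, b = NA_real_, d_r0 = NA_real_,
                       dd_r0 = NA_real_),
      sigma = NA_real_, vcov = NULL, objective = NA_real_, converged = FALSE,
      degenerate = FALSE, regime = NA_character_, t = t, d_r = d_r,
      fitted = rep(NA_real_, length(t)), seed = seed))
  }
  # Nelder-Mead polish off the box constraints for full precision
  polish <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(reltol = 1e-15, maxit = 2000))
  if (polish$value <= best$value &&
      all(polish$par >= lb - 1e-9) && all(polish$par <= ub + 1e-9)) {
    best <- polish
  }

  a <- exp(best$par[1])
  b <- exp(best$par[2])
  prof <- profile_rss(a, b, t, d_r)
  theta <- c(a = unname(a), b = unname(b), d_r0 = unname(prof$d0),
             dd_r0 = unname(prof$v0))
  n <- length(t)
  sigma <- sqrt(prof$rss / max(1, n - 4))
  vc <- fit_vcov(theta, t, sigma)
  new_cdt_fit(coefficients = theta, sigma = sigma, vcov = vc,
              objective = prof$rss, converged = any_conv, degenerate = FALSE,
              regime = damping_regime(dynamics_params(a, b), warn = FALSE),
              t = t, d_r = d_r, fitted = prof$fitted, seed = seed)
}

## closed-form basis for given (a, b); columns span the solution space
closed_form_basis <- function(a, b, t) {
  disc <- b^2 - 4 * a
  if (abs(disc) <= 1e-12 * max(1, b^2)) {
    r <- -b / 2
    cbind(exp(r * t), t * exp(r * t))
  } else if (disc > 0) {
    s <- sqrt(disc)
    cbind(exp((-b + s) / 2 * t), exp((-b - s) / 2 * t))
  } else {
    alpha <- b / 2
    omega <- sqrt(-disc) / 2
    cbind(exp(-alpha * t) * cos(omega * t), exp(-alpha * t) * sin(omega * t))
  }
}

## initial state implied by basis coefficients
basis_to_state <- function(a, b, cf) {
  disc <- b^2 - 4 * a
  if (abs(disc) <= 1e-12 * max(1, b^2)) {
    r <- -b / 2
    c(cf[1], r * cf[1] + cf[2])
  } else if (disc > 0) {
    s <- sqrt(disc)
    r1 <- (-b + s) / 2
    r2 <- (-b - s) / 2
    c(cf[1] + cf[2], r1 * cf[1] + r2 * cf[2])
  } else {
    alpha <- b / 2
    omega <- sqrt(-disc) / 2
    c(cf[1], -alpha * cf[1] + omega * cf[2])
  }
}

profile_rss <- function(a, b, t, d_r) {
  X <- closed_form_basis(a, b, t)
  fit <- stats::lm.fit(X, d_r)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  fitted <- as.numeric(X %*% cf)
  st <- basis_to_state(a, b, cf)
  list(rss = sum((d_r - fitted)^2), fitted = fitted, d0 = st[1], v0 = st[2])
}

## Gauss-Newton covariance from a forward-difference Jacobian of the model
## trajectory with respect to (a, b, d_r0, dd_r0)
fit_vcov <- function(theta, t, sigma) {
  f <- function(p) deviation_closed_form(p[1], p[2], p[3], p[4], t)
  base <- f(theta)
  J <- matrix(0, length(t), 4)
  for (j in 1:4) {
    h <- max(1e-6, 1e-6 * abs(theta[j]))
    pj <- theta
    pj[j] <- pj[j] + h
    J[, j] <- (f(pj) - base) / h
  }
  JtJ <- crossprod(J)
  vc <- tryCatch(sigma^2 * solve(JtJ), error = function(e) NULL)
  if (!is.null(vc)) dimnames(vc) <- list(names(theta), names(theta))
  vc
}

new_cdt_fit <- function(coefficients, sigma, vcov, objective, converged,
                        degenerate, regime, t, d_r, fitted, seed) {
  structure(list(coefficients = coefficients, sigma = sigma, vcov = vcov,
                 objective = objective, converged = converged,
                 degenerate = degenerate, regime = regime,
                 data = data.frame(t = t, d_r = d_r), fitted.values = fitted,
                 residuals = d_r - fitted, seed = seed),
            class = "cdt_fit")
}

#' @export
print.cdt_fit <- function(x, ...) {
  cat("Restoring-dynamics fit\n")
  if (x$degenerate) {
    cat("  degenerate: trajectory indistinguishable from zero; (a, b) not",
        "identifiable\n")
    return(invisible(x))
  }
  cat(sprintf("  a = %.6g, b = %.6g (%s); D_r0 = %.4g, dD_r0 = %.4g\n",
              x$coefficients["a"], x$coefficients["b"], x$regime,
              x$coefficients["d_r0"], x$coefficients["dd_r0"]))
  cat(sprintf("  RSS = %.4g, sigma = %.4g, converged: %s\n",
              x$objective, x$sigma, x$converged))
  invisible(x)
}

#' @export
summary.cdt_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, 4)
  tab <- data.frame(estimate = object$coefficients, std_error = se)
  out <- list(coefficients = tab, sigma = object$sigma,
              objective = object$objective, regime = object$regime,
              converged = object$converged, degenerate = object$degenerate,
              n = nrow(object$data))
  class(out) <- "summary.cdt_fit"
  out
}

#' @export
print.summary.cdt_fit <- function(x, ...) {
  cat("Restoring-dynamics fit\n")
  cat(sprintf("  n = %d samples; damping regime: %s\n", x$n, x$regime))
  print(round(x$coefficients, 6))
  cat(sprintf("  residual sd %.4g, RSS %.4g\n", x$sigma, x$objective))
  invisible(x)
}

#' @export
coef.cdt_fit <- function(object, ...) object$coefficients

#' @export
vcov.cdt_fit <- function(object, ...) object$vcov

#' @export
fitted.cdt_fit <- function(object, ...) object$fitted.values

#' @export
residuals.cdt_fit <- function(object, ...) object$residuals

#' Predicted deviation trajectory from a fit
#' @param object A `cdt_fit`.
#' @param t Times at which to evaluate (defaults to the fitted grid).
#' @param ... Unused.
#' @return Predicted `D_r(t)`.
#' @export
predict.cdt_fit <- function(object, t = NULL, ...) {
  if (object$degenerate) {
    stop("cannot predict from a degenerate fit", call. = FALSE)
  }
  if (is.null(t)) t <- object$data$t
  th <- object$coefficients
  deviation_closed_form(th["a"], th["b"], th["d_r0"], th["dd_r0"], t)
}

#' Simulate new noisy trajectories from a fit
#' @param object A `cdt_fit`.
#' @param nsim Number of replicate trajectories.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A matrix (`length(t)` x `nsim`) of simulated deviation samples.
#' @export
simulate.cdt_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  with_seed(seed, {
    matrix(stats::rnorm(length(mu) * nsim, mean = mu, sd = object$sigma),
           ncol = nsim)
  })
}

#' @export
plot.cdt_fit <- function(x, ...) {
  graphics::plot(x$data$t, x$data$d_r, pch = 16, cex = 0.6,
                 xlab = "time (s)", ylab = "relative deviation D_r", ...)
  graphics::lines(x$data$t, x$fitted.values, col = 2, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
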