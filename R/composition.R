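#' Per-system gain factors
#'
#' The total subjective-time gain is composed from cerebellar, basal-ganglia
#' and cortical component gains. All must be positive.
#'
#' @param kappa_cbl Cerebellar gain.
#' @param kappa_bg Basal-ganglia gain.
#' @param kappa_ctx Cortical gain.
#' @return An object of class `cdt_gains`.
#' @export
component_gains <- function(kappa_cbl = 1, kappa_bg = 1, kappa_ctx = 1) {
  check_gain(kappa_cbl)
  check_gain(kappa_bg)
  check_gain(kappa_ctx)
  structure(list(kappa_cbl = kappa_cbl, kappa_bg = kappa_bg,
                 kappa_ctx = kappa_ctx),
            class = "cdt_gains")
}

#' Comparator specification
#'
#' The cerebellum acts as an error-checking comparator between its own
#' timing signal and the integrated cortico-basal-ganglia state, pushing the
#' total gain toward 1. A comparator form must satisfy `C(1, 1) = 1`, and
#' with a neutral cerebellar gain the magnitude of the total log-gain must
#' be non-increasing in the comparator strength `g`. The default form is
#' `C = kappa_cbl^w_cbl * kappa_bgctx^(-g)`: at `g = 0` the comparator only
#' contributes the weighted cerebellar gain; at `g = 1` (with neutral
#' cerebellar gain) it cancels the cortico-basal-ganglia deviation entirely.
#' Alternative forms can be registered with [register_comparator()].
#'
#' @param g Comparator strength in `[0, 1]`.
#' @param form Name of a registered comparator form (default `"default"`).
#' @return An object of class `cdt_comparator`.
#' @export
comparator_spec <- function(g = 0, form = "default") {
  if (!is.finite(g) || g < 0 || g > 1) {
    stop("comparator strength `g` must be in [0, 1]", call. = FALSE)
  }
  if (!form %in% ls(comparator_registry)) {
    stop(sprintf("unknown comparator form '%s'; registered forms: %s",
                 form, paste(ls(comparator_registry), collapse = ", ")),
         call. = FALSE)
  }
  structure(list(g = g, form = form), class = "cdt_comparator")
}

comparator_registry <- new.env(parent = emptyenv())

#' Register a comparator form
#'
#' A form is a function `f(kappa_cbl, kappa_bgctx, g, weights)` returning a
#' positive correction factor, with `f(1, 1, g, w) = 1` for every `g` and
#' weight vector (checked at registration on a small grid).
#'
#' @param name Identifier for the form.
#' @param fn The comparator function.
#' @export
register_comparator <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  for (g in c(0, 0.5, 1)) {
    w <- weights_at(1, weight_profile())
    val <- fn(1, 1, g, w)
    if (!is.finite(val) || abs(val - 1) > 1e-12) {
      stop("comparator contract violated: C(1, 1) must equal 1", call. = FALSE)
    }
  }
  assign(name, fn, envir = comparator_registry)
  invisible(name)
}

#' Combined cortico-basal-ganglia gain
#'
#' The integrated non-cerebellar state entering the comparator, defined as
#' the weight-normalised geometric mean `kappa_bg^w_bg * kappa_ctx^w_ctx`.
#' This is the unique dimensionless choice consistent with both the
#' multiplicative and the log-linear composition.
#'
#' @param gains A [component_gains()] object.
#' @param weights One row of [weights_at()] (or a list with `w_bg`, `w_ctx`,
#'   `w_cbl`).
#' @return The combined background gain (positive scalar).
#' @export
combined_background_gain <- function(gains, weights) {
  gains <- as_gains(gains)
  gains$kappa_bg^weights$w_bg * gains$kappa_ctx^weights$w_ctx
}

#' Comparator correction factor
#'
#' Evaluates the registered comparator form for given cerebellar and
#' combined background gains.
#'
#' @param kappa_cbl Cerebellar gain (> 0).
#' @param kappa_bgctx Combined cortico-basal-ganglia gain (> 0).
#' @param spec A [comparator_spec()].
#' @param weights Weight row as in [combined_background_gain()].
#' @return Correction factor `C` (positive).
#' @export
comparator_correction <- function(kappa_cbl, kappa_bgctx,
                                  spec = comparator_spec(),
                                  weights = weights_at(1)) {
  check_gain(kappa_cbl)
  check_gain(kappa_bgctx)
  stopifnot(inherits(spec, "cdt_comparator"))
  fn <- get(spec$form, envir = comparator_registry)
  fn(kappa_cbl, kappa_bgctx, spec$g, weights)
}

#' Total gain, multiplicative composition
#'
#' `kappa = kappa_bg^w_bg * kappa_ctx^w_ctx * C(kappa_cbl, kappa_bgctx)`,
#' with weights evaluated at the interval duration being timed.
#'
#' @param gains A [component_gains()] object.
#' @param tau Interval duration, seconds, at which to evaluate the weights.
#' @param profile A [weight_profile()].
#' @param spec A [comparator_spec()].
#' @param weights Optional explicit weight row overriding
#'   `weights_at(tau, profile)` (constant-weight composition).
#' @return Total gain `kappa` (positive scalar).
#' @export
total_gain_multiplicative <- function(gains, tau = 1,
                                      profile = weight_profile(),
                                      spec = comparator_spec(),
                                      weights = NULL) {
  gains <- as_gains(gains)
  if (is.null(weights)) weights <- weights_at(tau, profile)
  bgctx <- combined_background_gain(gains, weights)
  bgctx * comparator_correction(gains$kappa_cbl, bgctx, spec, weights)
}

#' Total gain, log-linear composition
#'
#' The logarithm of the multiplicative composition:
#' `ln kappa = w_bg ln kappa_bg + w_ctx ln kappa_ctx + ln C`. The two forms
#' are exactly equivalent under `exp`/`log`.
#'
#' @inheritParams total_gain_multiplicative
#' @return `ln kappa` (scalar).
#' @export
total_gain_loglinear <- function(gains, tau = 1, profile = weight_profile(),
                                 spec = comparator_spec(), weights = NULL) {
  gains <- as_gains(gains)
  if (is.null(weights)) weights <- weights_at(tau, profile)
  bgctx <- combined_background_gain(gains, weights)
  weights$w_bg * log(gains$kappa_bg) + weights$w_ctx * log(gains$kappa_ctx) +
    log(comparator_correction(gains$kappa_cbl, bgctx, spec, weights))
}

#' Compose component gain trajectories into a total trajectory
#'
#' Applies the multiplicative composition sample-by-sample to three
#' component [gain_trajectory()] objects sharing one time grid; the derived
#' deviation and precision columns follow from the total gain.
#'
#' @param traj_cbl,traj_bg,traj_ctx Component [gain_trajectory()] objects on
#'   identical grids.
#' @inheritParams total_gain_multiplicative
#' @return A [gain_trajectory()] of the total gain.
#' @export
compose_trajectory <- function(traj_cbl, traj_bg, traj_ctx, tau = 1,
                               profile = weight_profile(),
                               spec = comparator_spec(), weights = NULL) {
  for (tr in list(traj_cbl, traj_bg, traj_ctx)) {
    stopifnot(inherits(tr, "cdt_trajectory"))
  }
  if (!isTRUE(all.equal(traj_cbl$t, traj_bg$t, tolerance = 0)) ||
      !isTRUE(all.equal(traj_cbl$t, traj_ctx$t, tolerance = 0))) {
    stop("component trajectories must share an identical time grid",
         call. = FALSE)
  }
  if (is.null(weights)) weights <- weights_at(tau, profile)
  n <- nrow(traj_cbl)
  kappa <- vapply(seq_len(n), function(i) {
    total_gain_multiplicative(
      component_gains(traj_cbl$kappa[i], traj_bg$kappa[i], traj_ctx$kappa[i]),
      weights = weights, spec = spec)
  }, numeric(1))
  gain_trajectory(traj_cbl$t, kappa - 1)
}

as_gains <- function(gains) {
  if (inherits(gains, "cdt_gains")) return(gains)
  if (is.list(gains) &&
      all(c("kappa_cbl", "kappa_bg", "kappa_ctx") %in% names(gains))) {
    return(component_gains(gains$kappa_cbl, gains$kappa_bg, gains$kappa_ctx))
  }
  stop("`gains` must be a `cdt_gains` object (see component_gains())",
       call. = FALSE)
}
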