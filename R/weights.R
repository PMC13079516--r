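#' Duration-dependent system weight profile
#'
#' Sub-second intervals are timed mainly by the cerebellum, supra-second
#' intervals increasingly by basal-ganglia accumulation, with a cortical
#' contribution peaking at intermediate durations. The profile realises
#' these constraints with a complementary logistic pair in `log10(tau)` for
#' the cerebellar/basal-ganglia weights (crossing at `tau_cross`) plus a
#' log-Gaussian cortical bump, all renormalised so the three weights sum to
#' one exactly at every duration.
#'
#' @param tau_cross Duration at which cerebellar and basal-ganglia weights
#'   cross, seconds (default 1).
#' @param slope Logistic steepness per `log10(tau)` unit (> 0).
#' @param ctx_center Centre of the cortical bump, `log10(tau)` units
#'   (default 0, i.e. 1 s).
#' @param ctx_width Bump width, `log10(tau)` units (> 0).
#' @param ctx_height Pre-normalisation bump amplitude (>= 0).
#' @return An object of class `cdt_weight_profile`.
#' @export
weight_profile <- function(tau_cross = 1, slope = 4, ctx_center = 0,
                           ctx_width = 0.5, ctx_height = 0.6) {
  check_positive(tau_cross, "tau_cross")
  check_positive(slope, "slope")
  check_positive(ctx_width, "ctx_width")
  if (!is.finite(ctx_center)) stop("`ctx_center` must be finite", call. = FALSE)
  if (!is.finite(ctx_height) || ctx_height < 0) {
    stop("`ctx_height` must be >= 0", call. = FALSE)
  }
  structure(list(tau_cross = tau_cross, slope = slope,
                 ctx_center = ctx_center, ctx_width = ctx_width,
                 ctx_height = ctx_height),
            class = "cdt_weight_profile")
}

#' System weights at an interval duration
#'
#' Evaluates the cerebellar, basal-ganglia and cortical weights at duration
#' `tau`. Weights are each in `[0, 1]` and sum to 1 exactly (raw values are
#' divided by their sum); the cerebellar weight is strictly decreasing in
#' `tau`, the basal-ganglia weight strictly increasing, and the cortical
#' weight unimodal with an interior maximum. At `tau = tau_cross` the
#' cerebellar and basal-ganglia weights are equal.
#'
#' @param tau Interval duration(s), seconds (> 0). Vectorised.
#' @param profile A [weight_profile()].
#' @return A data frame with columns `tau`, `w_cbl`, `w_bg`, `w_ctx`.
#' @examples
#' weights_at(c(0.1, 1, 10), weight_profile())
#' @export
weights_at <- function(tau, profile = weight_profile()) {
  stopifnot(inherits(profile, "cdt_weight_profile"))
  check_positive(tau, "tau")
  x <- log10(tau) - log10(profile$tau_cross)
  raw_cbl <- stats::plogis(-profile$slope * x)
  raw_bg <- 1 - raw_cbl
  raw_ctx <- profile$ctx_height *
    exp(-(log10(tau) - profile$ctx_center)^2 / (2 * profile$ctx_width^2))
  total <- raw_cbl + raw_bg + raw_ctx   # = 1 + raw_ctx
  data.frame(tau = tau,
             w_cbl = raw_cbl / total,
             w_bg = raw_bg / total,
             w_ctx = raw_ctx / total)
}

#' Crossover duration of the cerebellar and basal-ganglia weights
#'
#' Root-solves `w_cbl(tau) - w_bg(tau) = 0` on a duration bracket. Under the
#' default profile the crossover sits at the ~1 s transition between
#' cerebellar- and basal-ganglia-dominated timing.
#'
#' @param profile A [weight_profile()].
#' @param interval Search bracket in seconds (default `c(0.01, 100)`).
#' @param tol Root tolerance in seconds.
#' @return Crossover duration, seconds.
#' @export
weight_crossover <- function(profile = weight_profile(),
                             interval = c(0.01, 100), tol = 1e-6) {
  f <- function(tau) {
    w <- weights_at(tau, profile)
    w$w_cbl - w$w_bg
  }
  stats::uniroot(f, interval = interval, tol = tol)$root
}
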