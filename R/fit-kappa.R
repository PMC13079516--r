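#' Estimate the gain from interval-reproduction trials
#'
#' Inverts the reproduction model: with lognormal trial noise, the maximum
#' likelihood estimate of the encoding/readout gain ratio is the geometric
#' mean of the response/stimulus ratios. A seeded percentile bootstrap gives
#' the confidence interval.
#'
#' @param response Reproduced durations, seconds (> 0, >= 2 trials).
#' @param stimulus Objective stimulus durations, seconds (> 0; recycled).
#' @param level Confidence level (default 0.95).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Bootstrap seed.
#' @return A list of class `cdt_kappa_fit`: `kappa`, `ci`, `n`, `level`.
#' @examples
#' set.seed(1)
#' r <- reproduce_interval(1, kappa_enc = 0.8, noise_cv = 0.05, n = 100)
#' fit_kappa_reproduction(r, 1)$kappa
#' @export
fit_kappa_reproduction <- function(response, stimulus, level = 0.95,
                                   n_boot = 1000, seed = 1L) {
  if (length(response) < 2L) stop("need at least 2 trials", call. = FALSE)
  if (any(!is.finite(response)) || any(response <= 0)) {
    stop("responses must be finite and > 0", call. = FALSE)
  }
  check_positive(stimulus, "stimulus")
  lr <- log(response / stimulus)
  kappa <- exp(mean(lr))
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      exp(mean(sample(lr, replace = TRUE)))
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  structure(list(kappa = kappa, ci = ci, n = length(response), level = level),
            class = "cdt_kappa_fit")
}

#' @export
print.cdt_kappa_fit <- function(x, ...) {
  cat(sprintf("Gain estimate: kappa = %.4f (%g%% CI %.4f-%.4f, n = %d)\n",
              x$kappa, 100 * x$level, x$ci[1], x$ci[2], x$n))
  invisible(x)
}

#' Estimate the gain from an EEG spectral peak
#'
#' Inverts the frequency-scaling rule: the gain is the baseline peak
#' frequency divided by the observed peak, `kappa = f_base / f_obs`.
#'
#' @param readout A `cdt_psd` from [synth_psd()], or a list with `freq` and
#'   `power` (the peak is then detected with [detect_peak()]), or a single
#'   detected peak frequency in Hz.
#' @param f_base Baseline peak frequency, Hz (> 0).
#' @return Estimated gain.
#' @examples
#' fit_kappa_eeg(12.5, f_base = 10)  # 0.8
#' @export
fit_kappa_eeg <- function(readout, f_base) {
  check_positive(f_base, "f_base")
  f_obs <- if (inherits(readout, "cdt_psd")) {
    readout$f_peak_detected
  } else if (is.list(readout) && all(c("freq", "power") %in% names(readout))) {
    detect_peak(readout$freq, readout$power)
  } else if (is.numeric(readout) && length(readout) == 1L) {
    readout
  } else {
    stop("`readout` must be a cdt_psd, a freq/power list, or a peak frequency",
         call. = FALSE)
  }
  if (!is.finite(f_obs) || f_obs <= 0) {
    stop("no usable spectral peak in the readout", call. = FALSE)
  }
  f_base / f_obs
}

#' Parameter-recovery study
#'
#' Standard recovery harness: replicate datasets are generated at known
#' parameters, the estimator is applied to each, and bias, relative error
#' and RMSE are tabulated per parameter. Deterministic given the seeds.
#'
#' @param generator Function `generator(seed)` returning one dataset.
#' @param estimator Function `estimator(data)` returning a named numeric
#'   vector of estimates.
#' @param true Named numeric vector of the generating parameter values.
#' @param n_replicates Number of replicate datasets.
#' @param seeds Integer seeds, one per replicate (default `1:n_replicates`).
#' @return A data frame of class `cdt_recovery`: one row per parameter with
#'   `true`, `estimate` (mean), `bias`, `rel_error` (median absolute
#'   relative error), `rmse`, `variance`; per-replicate estimates in
#'   `attr(x, "estimates")`.
#' @export
recovery_study <- function(generator, estimator, true, n_replicates = 20,
                           seeds = seq_len(n_replicates)) {
  stopifnot(is.function(generator), is.function(estimator),
            is.numeric(true), !is.null(names(true)))
  if (length(seeds) != n_replicates) {
    stop("`seeds` must have one entry per replicate", call. = FALSE)
  }
  est <- vapply(seeds, function(s) {
    e <- estimator(generator(s))
    e[names(true)]
  }, numeric(length(true)))
  est <- if (is.null(dim(est))) matrix(est, ncol = 1L) else t(est)
  colnames(est) <- names(true)
  rows <- lapply(names(true), function(p) {
    e <- est[, p]
    bias <- mean(e) - true[[p]]
    vr <- mean((e - mean(e))^2)
    data.frame(parameter = p, true = true[[p]], estimate = mean(e),
               bias = bias,
               rel_error = stats::median(abs(e - true[[p]]) / abs(true[[p]])),
               rmse = sqrt(mean((e - true[[p]])^2)), variance = vr)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- est
  attr(out, "seeds") <- seeds
  class(out) <- c("cdt_recovery", "data.frame")
  out
}

#' @export
print.cdt_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates\n",
              nrow(attr(x, "estimates"))))
  print.data.frame(cbind(x[, "parameter", drop = FALSE],
                         round(x[, -1], 5)), row.names = FALSE)
  invisible(x)
}
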