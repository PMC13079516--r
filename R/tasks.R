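#' Simulate interval reproduction
#'
#' A presented duration is encoded at gain `kappa_enc` (the state under
#' study) and reproduced under readout gain `kappa_rep` (1 for a veridical
#' readout), giving a noiseless mean of `(kappa_enc / kappa_rep) * dt`:
#' compressed subjective time (`kappa_enc < 1`) yields short reproductions.
#' Trial noise is multiplicative lognormal with coefficient of variation
#' `noise_cv` (mean-preserving).
#'
#' @param dt Objective stimulus duration(s), seconds (> 0).
#' @param kappa_enc Gain at encoding (> 0).
#' @param kappa_rep Gain at reproduction (> 0, default 1).
#' @param noise_cv Coefficient of variation of the trial noise (>= 0).
#' @param n Number of trials per stimulus (ignored if `dt` is a vector of
#'   per-trial stimuli).
#' @return Numeric vector of reproduced durations, seconds.
#' @examples
#' set.seed(1)
#' mean(reproduce_interval(1, kappa_enc = 0.8, noise_cv = 0.1, n = 1000))
#' @export
reproduce_interval <- function(dt, kappa_enc, kappa_rep = 1, noise_cv = 0,
                               n = 1) {
  check_positive(dt, "dt")
  check_gain(kappa_enc)
  check_gain(kappa_rep)
  if (!is.finite(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be >= 0", call. = FALSE)
  }
  stim <- if (length(dt) > 1L) dt else rep(dt, n)
  mu <- (kappa_enc / kappa_rep) * stim
  if (noise_cv == 0) return(mu)
  sdlog <- sqrt(log(1 + noise_cv^2))
  mu * exp(stats::rnorm(length(mu), -sdlog^2 / 2, sdlog))
}

#' Simulate a temporal bisection block
#'
#' Probe durations between a short and a long anchor are judged "long" when
#' the subjectively scaled probe exceeds the criterion, taken as the
#' geometric mean of the anchors in subjective units:
#' `P(long | dt) = Phi((ln(kappa * dt) - ln B) / sigma_ln)` with
#' `B = sqrt(short * long)`. The objective bisection point (50% "long") is
#' therefore `B / kappa`: a dilated state (`kappa > 1`) judges every probe
#' longer and bisects at a shorter objective duration.
#'
#' @param short_anchor,long_anchor Anchor durations, seconds
#'   (`0 < short < long`).
#' @param probes Probe durations within `[short, long]`.
#' @param kappa Gain in force during the block (> 0).
#' @param sigma_ln Log-domain judgment noise sd (> 0).
#' @param n_per_probe Trials per probe.
#' @return A list of class `cdt_bisection`: `trials` (one row per trial:
#'   probe, choice 1 = "long"), `psychometric` (per-probe observed
#'   proportions and the model probability), `bp_true` (model bisection
#'   point `B / kappa`), and `bp_est` (probit-GLM estimate, `NA` if the fit
#'   is degenerate).
#' @export
bisection_block <- function(short_anchor, long_anchor, probes, kappa = 1,
                            sigma_ln = 0.2, n_per_probe = 50) {
  check_positive(short_anchor, "short_anchor")
  check_positive(long_anchor, "long_anchor")
  if (short_anchor >= long_anchor) {
    stop("`short_anchor` must be < `long_anchor`", call. = FALSE)
  }
  if (any(probes < short_anchor - 1e-12) || any(probes > long_anchor + 1e-12)) {
    stop("probes must lie within [short_anchor, long_anchor]", call. = FALSE)
  }
  check_gain(kappa)
  check_positive(sigma_ln, "sigma_ln")
  B <- sqrt(short_anchor * long_anchor)
  p_long <- stats::pnorm((log(kappa * probes) - log(B)) / sigma_ln)
  n_long <- stats::rbinom(length(probes), n_per_probe, p_long)
  trials <- data.frame(
    probe = rep(probes, each = n_per_probe),
    choice = unlist(lapply(seq_along(probes), function(i) {
      sample(rep(c(1L, 0L), c(n_long[i], n_per_probe - n_long[i])))
    }))
  )
  psych <- data.frame(probe = probes, n = n_per_probe, n_long = n_long,
                      p_long_obs = n_long / n_per_probe, p_long_model = p_long)
  bp_est <- tryCatch({
    fit <- stats::glm(cbind(n_long, n - n_long) ~ log(probe), data = psych,
                      family = stats::binomial("probit"))
    cf <- stats::coef(fit)
    if (cf[2] > 0) unname(exp(-cf[1] / cf[2])) else NA_real_
  }, error = function(e) NA_real_, warning = function(w) {
    suppressWarnings({
      fit <- stats::glm(cbind(n_long, n - n_long) ~ log(probe), data = psych,
                        family = stats::binomial("probit"))
      cf <- stats::coef(fit)
      if (cf[2] > 0) unname(exp(-cf[1] / cf[2])) else NA_real_
    })
  })
  structure(list(trials = trials, psychometric = psych,
                 anchors = c(short_anchor, long_anchor), kappa = kappa,
                 sigma_ln = sigma_ln, bp_true = B / kappa, bp_est = bp_est),
            class = "cdt_bisection")
}

#' @export
print.cdt_bisection <- function(x, ...) {
  cat(sprintf(
    "Bisection block: anchors %g-%g s, kappa = %g\n", x$anchors[1],
    x$anchors[2], x$kappa))
  cat(sprintf("  model bisection point %.4f s, estimated %.4f s\n",
              x$bp_true, x$bp_est))
  invisible(x)
}

#' Simulate continuation-phase rhythmic tapping
#'
#' Inter-tap intervals in the continuation phase have mean
#' `(kappa_enc / kappa_rep) * target_period` and a coefficient of variation
#' `cv0 + c * |d_r|`: a baseline motor floor plus a precision-linked term —
#' as timing precision falls (larger `|d_r|`), tap variability rises.
#' Intervals are lognormal (positive, mean- and CV-exact).
#'
#' @param target_period Target inter-tap interval, seconds (> 0).
#' @param kappa_enc,kappa_rep Encoding and readout gains (> 0).
#' @param cv0 Baseline coefficient of variation (>= 0).
#' @param c_slope Precision-coupling slope (>= 0).
#' @param d_r Relative deviation of the state (sets the CV increment).
#' @param n_taps Number of inter-tap intervals.
#' @return Numeric vector of inter-tap intervals, seconds, with the model CV
#'   in attribute `"cv_model"`.
#' @export
tapping_series <- function(target_period, kappa_enc = 1, kappa_rep = 1,
                           cv0 = 0.05, c_slope = 0.5, d_r = 0, n_taps = 100) {
  check_positive(target_period, "target_period")
  check_gain(kappa_enc)
  check_gain(kappa_rep)
  if (!is.finite(cv0) || cv0 < 0) stop("`cv0` must be >= 0", call. = FALSE)
  if (!is.finite(c_slope) || c_slope < 0) {
    stop("`c_slope` must be >= 0", call. = FALSE)
  }
  if (!is.finite(d_r)) stop("`d_r` must be finite", call. = FALSE)
  cv <- cv0 + c_slope * abs(d_r)
  mu <- (kappa_enc / kappa_rep) * target_period
  iti <- if (cv == 0) {
    rep(mu, n_taps)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    mu * exp(stats::rnorm(n_taps, -sdlog^2 / 2, sdlog))
  }
  attr(iti, "cv_model") <- cv
  iti
}

#' EEG spectral peak under a gain state
#'
#' Clock periods scale by `kappa`, so oscillation frequencies scale by
#' `1 / kappa`: an individual's baseline spectral peak `f_base` is observed
#' at `f_base / kappa`. Compression (`kappa < 1`) raises the peak.
#'
#' @param f_base Baseline peak frequency, Hz (> 0).
#' @param kappa Gain (> 0).
#' @return Observed peak frequency, Hz.
#' @examples
#' eeg_peak_frequency(10, 0.8)  # 12.5 Hz
#' @export
eeg_peak_frequency <- function(f_base, kappa) {
  check_positive(f_base, "f_base")
  check_gain(kappa)
  f_base / kappa
}

#' Synthesise a unimodal power spectrum
#'
#' A Gaussian spectral bump at `f_peak` on a `1/f` background with additive
#' Gaussian noise (clipped at zero) — a minimal stand-in for a resting power
#' spectral density whose alpha-band peak carries the gain readout. The
#' detected peak is located by [detect_peak()] on the noisy spectrum.
#'
#' @param f_peak True peak frequency, Hz (inside the grid).
#' @param freq Frequency grid, Hz (strictly increasing, > 0).
#' @param width Bump width (Gaussian sd), Hz (> 0).
#' @param amplitude Bump height (arbitrary units, > 0).
#' @param background Scale of the `1/f` background (>= 0).
#' @param noise_sd Additive noise sd (>= 0).
#' @return A list of class `cdt_psd`: `freq`, `power`, `f_peak_true`,
#'   `f_peak_detected`.
#' @export
synth_psd <- function(f_peak, freq = seq(2, 30, by = 0.1), width = 1,
                      amplitude = 1, background = 0.05, noise_sd = 0.05) {
  check_positive(freq, "freq")
  check_grid(freq)
  if (f_peak < freq[1] || f_peak > freq[length(freq)]) {
    stop(sprintf("f_peak = %g Hz lies outside the frequency grid [%g, %g]",
                 f_peak, freq[1], freq[length(freq)]), call. = FALSE)
  }
  check_positive(width, "width")
  check_positive(amplitude, "amplitude")
  clean <- amplitude * exp(-(freq - f_peak)^2 / (2 * width^2)) +
    background / freq
  power <- pmax(clean + stats::rnorm(length(freq), 0, noise_sd), 0)
  structure(list(freq = freq, power = power, f_peak_true = f_peak,
                 f_peak_detected = detect_peak(freq, power)),
            class = "cdt_psd")
}

#' Locate the dominant spectral peak
#'
#' Smooths the spectrum with a short moving average, takes the argmax, and
#' refines it by quadratic interpolation through the three smoothed samples
#' around the maximum. Deterministic given the data.
#'
#' @param freq Frequency grid, Hz.
#' @param power Power values (same length).
#' @param smooth Moving-average window (odd integer, default 9).
#' @return Peak frequency, Hz.
#' @export
detect_peak <- function(freq, power, smooth = 9) {
  stopifnot(length(freq) == length(power), length(freq) >= 3)
  k <- max(1L, as.integer(smooth))
  if (k %% 2L == 0L) k <- k + 1L
  sm <- stats::filter(power, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- power[is.na(sm)]
  i <- which.max(sm)
  if (i == 1L || i == length(freq)) return(freq[i])
  y1 <- sm[i - 1]; y2 <- sm[i]; y3 <- sm[i + 1]
  denom <- y1 - 2 * y2 + y3
  if (denom == 0) return(freq[i])
  delta <- 0.5 * (y1 - y3) / denom
  delta <- max(-0.5, min(0.5, delta))
  freq[i] + delta * (freq[i] - freq[i - 1])
}

#' Generate a synthetic task dataset under a gain regime
#'
#' Batch wrapper producing a trial table for one of the four tasks under a
#' given gain. The gain can be passed directly, or derived from a
#' [preset()] / `cdt_scenario` (total gain composed at the task's interval
#' duration, comparator disabled so the pathological state is observed).
#' The generative parameters are recorded in the `"ground_truth"` attribute
#' for parameter-recovery checks.
#'
#' @param task One of `"reproduction"`, `"bisection"`, `"tapping"`, `"eeg"`.
#' @param regime A gain value, a [preset()], or a `cdt_scenario`.
#' @param n_trials Trials (>= 1).
#' @param seed Integer seed.
#' @param durations Stimulus duration (reproduction), anchor pair
#'   (bisection), target period (tapping) or base frequency in Hz (eeg).
#' @param noise Per-task noise parameter: `noise_cv` (reproduction),
#'   `sigma_ln` (bisection), `cv0` (tapping), `noise_sd` (eeg).
#' @param profile Weight profile used when deriving the gain from a preset.
#' @return A data frame (class `cdt_trials`) with columns
#'   `task, condition, stimulus, response`; ground truth in
#'   `attr(x, "ground_truth")`.
#' @export
generate_task_dataset <- function(task = c("reproduction", "bisection",
                                           "tapping", "eeg"),
                                  regime = 1, n_trials = 100, seed = 1L,
                                  durations = NULL, noise = NULL,
                                  profile = weight_profile()) {
  task <- match.arg(task)
  if (!is.numeric(n_trials) || n_trials < 1) {
    stop("`n_trials` must be >= 1", call. = FALSE)
  }
  durations <- switch(task,
    reproduction = durations %||% 1,
    bisection = durations %||% c(1, 9),
    tapping = durations %||% 0.4,
    eeg = durations %||% 10)
  noise <- switch(task,
    reproduction = noise %||% 0.1,
    bisection = noise %||% 0.2,
    tapping = noise %||% 0.05,
    eeg = noise %||% 0.05)
  tau <- switch(task, bisection = mean(durations), eeg = 1, durations[1])
  kappa <- regime_gain(regime, tau, profile)
  condition <- regime_label(regime)

  out <- with_seed(seed, switch(task,
    reproduction = {
      resp <- reproduce_interval(durations[1], kappa_enc = kappa,
                                 noise_cv = noise, n = n_trials)
      data.frame(task = task, condition = condition, stimulus = durations[1],
                 response = resp)
    },
    bisection = {
      probes <- exp(seq(log(durations[1]), log(durations[2]), length.out = 7))
      npp <- max(1L, floor(n_trials / length(probes)))
      blk <- bisection_block(durations[1], durations[2], probes, kappa = kappa,
                             sigma_ln = noise, n_per_probe = npp)
      data.frame(task = task, condition = condition,
                 stimulus = blk$trials$probe, response = blk$trials$choice)
    },
    tapping = {
      d_r <- kappa - 1
      iti <- tapping_series(durations[1], kappa_enc = kappa, cv0 = noise,
                            d_r = d_r, n_taps = n_trials)
      data.frame(task = task, condition = condition, stimulus = durations[1],
                 response = as.numeric(iti))
    },
    eeg = {
      f_obs <- eeg_peak_frequency(durations[1], kappa)
      psd <- synth_psd(f_obs, noise_sd = noise)
      data.frame(task = task, condition = condition, stimulus = psd$freq,
                 response = psd$power)
    }))
  attr(out, "ground_truth") <- list(task = task, kappa = kappa,
                                    durations = durations, noise = noise,
                                    seed = seed)
  class(out) <- c("cdt_trials", "data.frame")
  out
}

regime_gain <- function(regime, tau, profile) {
  if (is.numeric(regime)) {
    check_gain(regime)
    return(regime)
  }
  if (inherits(regime, "cdt_scenario")) return(mean(regime$total$kappa))
  if (inherits(regime, "cdt_preset")) {
    g <- regime$gains
    if (anyNA(unlist(g))) {
      stop("preset has unstable components; simulate a scenario first and ",
           "pass the cdt_scenario", call. = FALSE)
    }
    w <- weights_at(tau, profile)
    return(total_gain_multiplicative(
      component_gains(g$kappa_cbl, g$kappa_bg, g$kappa_ctx),
      weights = w, spec = comparator_spec(0)))
  }
  stop("`regime` must be a gain, cdt_preset or cdt_scenario", call. = FALSE)
}

regime_label <- function(regime) {
  if (inherits(regime, "cdt_preset")) return(regime$name)
  if (inherits(regime, "cdt_scenario")) return(regime$preset$name)
  sprintf("kappa=%g", regime)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
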