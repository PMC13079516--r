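## Table of disorder regimes: per-system direction of ln kappa
## (-1 compressed, 0 neutral, +1 dilated, "unstable" stochastic), the
## qualitative precision level, and the distortion summary the regime should
## classify back to.
disorder_table <- list(
  schizophrenia = list(cbl = "unstable", bg = 0, ctx = "unstable",
                       precision_level = "low", distortion = "unstable"),
  bipolar_mania = list(cbl = -1, bg = 0, ctx = -1,
                       precision_level = "normal", distortion = "compressed"),
  bipolar_depression = list(cbl = 0, bg = 1, ctx = 1,
                            precision_level = "low", distortion = "dilated"),
  major_depression = list(cbl = 0, bg = 1, ctx = 1,
                          precision_level = "low", distortion = "dilated"),
  anxiety_ptsd = list(cbl = 1, bg = 1, ctx = 1,
                      precision_level = "low", distortion = "dilated"),
  asd = list(cbl = "unstable", bg = "unstable", ctx = "unstable",
             precision_level = "unstable", distortion = "unstable"),
  parkinsonism = list(cbl = -1, bg = 1, ctx = 1,
                      precision_level = "low", distortion = "dilated")
)

#' Disorder-regime preset
#'
#' Encodes a disorder's hypothesised per-system gain directions as a
#' concrete parameterisation: systems marked dilated/compressed get constant
#' gains `exp(+/- delta)`, neutral systems stay at 1, and "unstable" systems
#' get a seeded mean-zero Ornstein-Uhlenbeck process on `ln kappa`
#' (stationary sd `instability_sd`, correlation time 2 s) — temporal jitter
#' rather than a fixed bias. Only the signs come from the disorder mapping;
#' the magnitude `delta` is a user parameter.
#'
#' Available regimes: schizophrenia, bipolar_mania, bipolar_depression,
#' major_depression, anxiety_ptsd, asd, parkinsonism. The anxiety/PTSD bias
#' is threat-locked: by default the whole run counts as a threat epoch, and
#' `threat_epochs` can restrict the bias to given `[start, end]` windows.
#'
#' @param name Regime name (see above).
#' @param delta Magnitude of `|ln kappa|` for non-neutral systems (> 0,
#'   default 0.2).
#' @param instability_sd Stationary sd of `ln kappa` for unstable systems
#'   (default 0.5).
#' @param seed Integer seed for the unstable-system processes.
#' @param threat_epochs Optional two-column matrix of `[start, end]` times
#'   (seconds) during which a threat-biased gain applies (anxiety/PTSD
#'   only); `NULL` means the bias is tonic over the run.
#' @return An object of class `cdt_preset`.
#' @examples
#' preset("bipolar_mania")$gains$kappa_cbl  # exp(-0.2)
#' @export
preset <- function(name, delta = 0.2, instability_sd = 0.5, seed = 1L,
                   threat_epochs = NULL) {
  if (!name %in% names(disorder_table)) {
    stop(sprintf("unknown disorder regime '%s'; available: %s", name,
                 paste(names(disorder_table), collapse = ", ")),
         call. = FALSE)
  }
  check_positive(delta, "delta")
  check_positive(instability_sd, "instability_sd")
  row <- disorder_table[[name]]
  const_gain <- function(dir) {
    if (identical(dir, "unstable")) NA_real_ else exp(as.numeric(dir) * delta)
  }
  gains <- list(kappa_cbl = const_gain(row$cbl),
                kappa_bg = const_gain(row$bg),
                kappa_ctx = const_gain(row$ctx))
  structure(list(name = name, directions = row[c("cbl", "bg", "ctx")],
                 precision_level = row$precision_level,
                 distortion = row$distortion,
                 delta = delta, instability_sd = instability_sd,
                 seed = as.integer(seed), threat_epochs = threat_epochs,
                 gains = gains),
            class = "cdt_preset")
}

#' Null (neutral) preset
#'
#' All component gains at 1: veridical timing, used as the healthy baseline.
#' @inheritParams preset
#' @return A `cdt_preset` with all-neutral directions.
#' @export
null_preset <- function(seed = 1L) {
  structure(list(name = "null", directions = list(cbl = 0, bg = 0, ctx = 0),
                 precision_level = "normal", distortion = "normal",
                 delta = 0, instability_sd = 0, seed = as.integer(seed),
                 threat_epochs = NULL,
                 gains = list(kappa_cbl = 1, kappa_bg = 1, kappa_ctx = 1)),
            class = "cdt_preset")
}

#' @export
print.cdt_preset <- function(x, ...) {
  cat(sprintf("Disorder preset '%s' (delta = %g)\n", x$name, x$delta))
  for (sys in c("cbl", "bg", "ctx")) {
    d <- x$directions[[sys]]
    lab <- if (identical(d, "unstable")) {
      sprintf("unstable (OU sd %g on ln kappa)", x$instability_sd)
    } else {
      sprintf("kappa = %.4f", exp(as.numeric(d) * x$delta))
    }
    cat(sprintf("  %-3s: %s\n", toupper(sys), lab))
  }
  cat(sprintf("  expected regime: %s, precision %s\n",
              x$distortion, x$precision_level))
  invisible(x)
}

## ln-kappa series per system on a grid, seeded per (preset seed, system)
preset_log_gain_series <- function(prst, t) {
  stopifnot(inherits(prst, "cdt_preset"))
  out <- list()
  for (sys in c("cbl", "bg", "ctx")) {
    d <- prst$directions[[sys]]
    if (identical(d, "unstable")) {
      s <- child_seed(prst$seed, paste0("preset-", prst$name, "-", sys))
      out[[sys]] <- with_seed(s, ou_series(t, prst$instability_sd, 2))
    } else {
      lk <- rep(as.numeric(d) * prst$delta, length(t))
      if (prst$name == "anxiety_ptsd" && !is.null(prst$threat_epochs)) {
        inside <- rep(FALSE, length(t))
        ep <- prst$threat_epochs
        for (k in seq_len(nrow(ep))) {
          inside <- inside | (t >= ep[k, 1] & t <= ep[k, 2])
        }
        lk[!inside] <- 0
      }
      out[[sys]] <- lk
    }
  }
  out
}
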