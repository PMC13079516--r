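## deterministic child-seed derivation: a named stream from a master seed,
## so adding a stream never perturbs existing ones
child_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 1000003
  as.integer((abs(master) + h * 2011) %% .Machine$integer.max)
}

## run `expr` under a local RNG state seeded with `seed`; NULL seed leaves the
## global stream untouched
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## stationary Ornstein-Uhlenbeck samples on a (possibly irregular) grid
ou_series <- function(t, sd, tau_corr) {
  n <- length(t)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  if (n > 1L) {
    for (i in 2:n) {
      rho <- exp(-(t[i] - t[i - 1]) / tau_corr)
      x[i] <- x[i - 1] * rho + sd * sqrt(1 - rho^2) * stats::rnorm(1)
    }
  }
  x
}
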