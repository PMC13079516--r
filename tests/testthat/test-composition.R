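test_that("weights are normalised, bounded and cross at tau_cross", {
  prof <- weight_profile()
  taus <- 10^seq(-2, 2, length.out = 200)
  w <- weights_at(taus, prof)
  expect_true(all(w$w_cbl >= 0 & w$w_cbl <= 1))
  expect_true(all(w$w_bg >= 0 & w$w_bg <= 1))
  expect_true(all(w$w_ctx >= 0 & w$w_ctx <= 1))
  expect_lt(max(abs(w$w_cbl + w$w_bg + w$w_ctx - 1)), 1e-12)
  # crossover at 1 s under the default profile
  w1 <- weights_at(1, prof)
  expect_equal(w1$w_cbl, w1$w_bg, tolerance = 1e-12)
  expect_equal(weight_crossover(prof), 1, tolerance = 1e-5)
  # non-default crossover moves with tau_cross
  expect_equal(weight_crossover(weight_profile(tau_cross = 2.5)), 2.5,
               tolerance = 1e-4)
  # sub-second cerebellar dominance, supra-second basal-ganglia dominance
  expect_gt(weights_at(0.05, prof)$w_cbl, weights_at(0.05, prof)$w_bg)
  expect_gt(weights_at(20, prof)$w_bg, weights_at(20, prof)$w_cbl)
  expect_error(weights_at(0, prof), "tau")
})

test_that("weight functions are monotone (CBL down, BG up) with unimodal CTX", {
  w <- weights_at(10^seq(-2, 2, length.out = 400), weight_profile())
  expect_true(all(diff(w$w_cbl) < 0))
  expect_true(all(diff(w$w_bg) > 0))
  d <- diff(w$w_ctx)
  expect_equal(sum(diff(sign(d[d != 0])) != 0), 1)  # single interior argmax
  i_max <- which.max(w$w_ctx)
  expect_true(i_max > 1 && i_max < nrow(w))
})

test_that("combined background gain is the weighted geometric mean", {
  w55 <- list(w_cbl = 0, w_bg = 0.5, w_ctx = 0.5)
  expect_equal(combined_background_gain(component_gains(1, 1, 1), w55), 1)
  expect_equal(
    combined_background_gain(component_gains(1, 2, 1), w55), sqrt(2))
  expect_equal(
    combined_background_gain(component_gains(1, 2, 0.5), w55), 1)
})

test_that("comparator obeys its contract and the default form cancels at g = 1", {
  w <- weights_at(1)
  for (g in c(0, 0.5, 1)) {
    expect_equal(comparator_correction(1, 1, comparator_spec(g), w), 1)
  }
  # g = 1 fully corrects a background deviation when CBL is neutral
  k_full <- total_gain_multiplicative(component_gains(1, 1.5, 1.5),
                                      spec = comparator_spec(1),
                                      weights = list(w_cbl = 0, w_bg = 0.5,
                                                     w_ctx = 0.5))
  expect_equal(k_full, 1)
  # g = 0 leaves the background gain uncorrected
  k_none <- total_gain_multiplicative(component_gains(1, 1.5, 1.5),
                                      spec = comparator_spec(0),
                                      weights = list(w_cbl = 0, w_bg = 0.5,
                                                     w_ctx = 0.5))
  expect_equal(k_none, 1.5)
  # |ln kappa| non-increasing in g with neutral CBL, both signs of deviation
  for (bg in c(0.6, 1.8)) {
    lk <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(g) {
      abs(total_gain_loglinear(component_gains(1, bg, bg),
                               spec = comparator_spec(g), weights = w))
    })
    expect_true(all(diff(lk) <= 1e-12))
  }
  expect_error(comparator_spec(1.5), "\\[0, 1\\]")
  expect_error(comparator_spec(0, form = "nope"), "unknown comparator")
  expect_error(register_comparator("bad", function(kc, kb, g, w) 2),
               "contract")
})

test_that("multiplicative and log-linear compositions are exp/log equivalent", {
  prof <- weight_profile()
  set.seed(101)
  for (i in 1:1000) {
    gains <- component_gains(exp(rnorm(1, 0, 0.4)), exp(rnorm(1, 0, 0.4)),
                             exp(rnorm(1, 0, 0.4)))
    tau <- 10^runif(1, -2, 2)
    g <- runif(1)
    mult <- total_gain_multiplicative(gains, tau, prof, comparator_spec(g))
    loglin <- total_gain_loglinear(gains, tau, prof, comparator_spec(g))
    expect_equal(exp(loglin), mult, tolerance = 1e-12)
  }
  # all-unity gains give kappa = 1 and infinite precision at any tau
  for (tau in c(0.05, 1, 30)) {
    k <- total_gain_multiplicative(component_gains(1, 1, 1), tau, prof,
                                   comparator_spec(0.7))
    expect_equal(k, 1)
    expect_identical(precision(relative_deviation(k)), Inf)
  }
})

test_that("trajectory composition equals the scalar operation per sample", {
  t <- seq(0, 2, by = 0.1)
  c1 <- gain_trajectory(t, rep(0, length(t)))
  flat <- compose_trajectory(c1, c1, c1, tau = 1)
  expect_true(all(flat$kappa == 1))
  # constant BG gain with ramping comparator strength: kappa ramps toward 1
  bg <- gain_trajectory(t, rep(0.5, length(t)))
  ks <- sapply(seq(0, 1, 0.25), function(g) {
    compose_trajectory(c1, bg, c1, spec = comparator_spec(g),
                       weights = list(w_cbl = 0, w_bg = 1, w_ctx = 0))$kappa[1]
  })
  expect_equal(ks[1], 1.5)
  expect_equal(ks[5], 1)
  expect_true(all(diff(ks) < 0))
  # pointwise agreement with the scalar op on varying trajectories
  set.seed(7)
  tc <- gain_trajectory(t, rnorm(length(t), 0, 0.1))
  tb <- gain_trajectory(t, rnorm(length(t), 0, 0.1))
  tx <- gain_trajectory(t, rnorm(length(t), 0, 0.1))
  comp <- compose_trajectory(tc, tb, tx, tau = 0.5, spec = comparator_spec(0.3))
  w <- weights_at(0.5)
  manual <- sapply(seq_along(t), function(i) {
    total_gain_multiplicative(
      component_gains(tc$kappa[i], tb$kappa[i], tx$kappa[i]),
      weights = w, spec = comparator_spec(0.3))
  })
  expect_equal(comp$kappa, manual, tolerance = 1e-14)
  # grid mismatch is an error
  short <- gain_trajectory(t[-1], rep(0, length(t) - 1))
  expect_error(compose_trajectory(c1, c1, short), "grid")
})
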