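all_regimes <- c("schizophrenia", "bipolar_mania", "bipolar_depression",
                 "major_depression", "anxiety_ptsd", "asd", "parkinsonism")

test_that("presets encode the hypothesised gain directions", {
  m <- preset("bipolar_mania", delta = 0.2)
  expect_equal(m$gains$kappa_cbl, exp(-0.2))
  expect_lt(m$gains$kappa_cbl, 1)
  expect_lt(m$gains$kappa_ctx, 1)
  expect_equal(m$gains$kappa_bg, 1)
  d <- preset("major_depression", delta = 0.2)
  expect_equal(d$gains$kappa_bg, exp(0.2))
  expect_gt(d$gains$kappa_bg, 1)
  expect_gt(d$gains$kappa_ctx, 1)
  pk <- preset("parkinsonism")
  expect_lt(pk$gains$kappa_cbl, 1)
  expect_gt(pk$gains$kappa_bg, 1)
  expect_gt(pk$gains$kappa_ctx, 1)
  expect_true(is.na(preset("schizophrenia")$gains$kappa_cbl))  # stochastic
  expect_error(preset("nonsense"), "unknown disorder")
})

test_that("unstable components are seeded mean-zero processes, reproducible", {
  s1 <- simulate_scenario(preset("schizophrenia", seed = 7))
  s2 <- simulate_scenario(preset("schizophrenia", seed = 7))
  expect_identical(s1$total$d_r, s2$total$d_r)
  s3 <- simulate_scenario(preset("schizophrenia", seed = 8))
  expect_false(identical(s1$total$d_r, s3$total$d_r))
  # jitter, not bias: sign changes present, BG stays neutral
  expect_gt(sum(diff(sign(s1$components$cbl$d_r)) != 0), 3)
  expect_true(all(s1$components$bg$d_r == 0))
})

test_that("null scenario is veridical; depression dilates; comparator corrects", {
  sc0 <- simulate_scenario(null_preset())
  expect_true(all(sc0$total$kappa == 1))
  expect_true(all(abs(sc0$total$d_r) == 0))
  expect_equal(sc0$classification$distortion, "normal")
  dep <- simulate_scenario(preset("major_depression"),
                           spec = comparator_spec(0))
  expect_gt(mean(dep$total$kappa), 1)
  # raising g shrinks the deviation (CBL neutral in this preset)
  dep1 <- simulate_scenario(preset("major_depression"),
                            spec = comparator_spec(1))
  expect_lt(mean(abs(dep1$total$d_r)), mean(abs(dep$total$d_r)))
})

test_that("every disorder preset classifies back to its own regime", {
  for (nm in all_regimes) {
    p <- preset(nm, delta = 0.2, seed = 11)
    cl <- simulate_scenario(p)$classification
    expect_equal(cl$distortion, p$distortion, label = nm)
    expect_equal(cl$precision_level, p$precision_level, label = nm)
  }
})

test_that("parkinsonism flips sign across the sub/supra-second boundary", {
  pk <- preset("parkinsonism")
  sub <- simulate_scenario(pk, tau = 0.3)
  supra <- simulate_scenario(pk, tau = 3)
  expect_lt(mean(sub$total$d_r), 0)     # compressed sub-second
  expect_gt(mean(supra$total$d_r), 0)   # dilated supra-second
})

test_that("threat epochs restrict the anxiety bias to scheduled windows", {
  t <- seq(0, 30, by = 0.05)
  ep <- matrix(c(5, 10), nrow = 1)
  p <- preset("anxiety_ptsd", threat_epochs = ep)
  sc <- simulate_scenario(p, t = t)
  inside <- t >= 5 & t <= 10
  expect_true(all(sc$total$d_r[inside] > 0))
  expect_true(all(sc$total$d_r[!inside] == 0))
  # tonic by default
  tonic <- simulate_scenario(preset("anxiety_ptsd"), t = t)
  expect_true(all(tonic$total$d_r > 0))
})

test_that("interventions edit parameters from onset with bound checks", {
  dep <- simulate_scenario(preset("major_depression"),
                           spec = comparator_spec(0))
  # full comparator engagement restores kappa = 1 after onset (CBL neutral)
  fixed <- apply_intervention(dep, intervention_spec("comparator_gain",
                                                     delta = 1, onset = 10))
  post <- fixed$grid >= 10   # effect includes the onset sample
  expect_equal(fixed$total$kappa[post], rep(1, sum(post)), tolerance = 1e-12)
  expect_equal(fixed$total$kappa[!post], dep$total$kappa[!post])
  # zero-delta intervention is the identity
  same <- apply_intervention(dep, intervention_spec("comparator_gain",
                                                    delta = 0, onset = 10))
  expect_identical(same$total$d_r, dep$total$d_r)
  # damping increase moves an underdamped law toward overdamped
  und <- simulate_scenario(null_preset(), params = dynamics_params(4, 2),
                           challenge = challenge_protocol(2, 3, 0.5))
  stiff <- apply_intervention(und, intervention_spec("damping_b", delta = 4,
                                                     onset = 8))
  expect_equal(und$damping, "underdamped")
  expect_true("overdamped" %in% stiff$damping)
  # bound violations are configuration errors
  expect_error(apply_intervention(dep, intervention_spec("comparator_gain",
                                                         delta = 2)),
               "outside")
  expect_error(apply_intervention(dep, intervention_spec("restoring_a",
                                                         delta = -5)),
               "<= 0")
  expect_error(intervention_spec("component_kappa", delta = 0.1), "system")
})

test_that("component-gain interventions shift the targeted system only", {
  dep <- simulate_scenario(preset("major_depression"),
                           spec = comparator_spec(0))
  shifted <- apply_intervention(dep, intervention_spec("component_kappa",
                                                       delta = -0.2,
                                                       system = "bg",
                                                       onset = 15))
  post <- shifted$grid >= 15
  expect_equal(shifted$components$bg$kappa[post],
               rep(1, sum(post)), tolerance = 1e-12)  # exp(0.2 - 0.2)
  expect_equal(shifted$components$ctx$kappa, dep$components$ctx$kappa)
  expect_lt(mean(shifted$total$d_r[post]), mean(dep$total$d_r[post]))
})

test_that("steady-state |ln kappa| is non-increasing in comparator strength", {
  for (nm in c("major_depression", "bipolar_depression")) {
    p0 <- preset(nm)
    lk <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(g) {
      sc <- simulate_scenario(p0, spec = comparator_spec(g))
      abs(mean(log(sc$total$kappa)))
    })
    expect_true(all(diff(lk) <= 1e-12), label = nm)
  }
})
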