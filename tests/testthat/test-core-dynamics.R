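test_that("gain relations scale intervals, periods and deviations", {
  # dilation, identity and compression of an objective interval
  expect_equal(subjective_interval(1, 2), 2)
  expect_equal(subjective_interval(1.5, 2), 3)
  expect_equal(subjective_interval(0.5, 2), 1)
  # same scaling for clock periods
  expect_equal(subjective_period(1, 0.1), 0.1)
  expect_equal(subjective_period(1.2, 0.1), 0.12)
  expect_equal(subjective_period(0.8, 0.1), 0.08)
  # absolute and relative deviation
  expect_equal(absolute_deviation(0.12, 0.1), 0.02)
  expect_equal(absolute_deviation(0.1, 0.1), 0)
  expect_equal(absolute_deviation(0.08, 0.1), -0.02)
  expect_equal(relative_deviation(1), 0)
  expect_equal(relative_deviation(1.2), 0.2)
  expect_equal(relative_deviation(0.7), -0.3)
  # domain errors
  expect_error(subjective_interval(-1, 2), "kappa")
  expect_error(subjective_interval(1, -2), "dt")
  expect_error(relative_deviation(0), "kappa")
  expect_error(absolute_deviation(-0.1, 0.1), "tau_s")
})

test_that("precision is the reciprocal absolute deviation with Inf at zero", {
  expect_equal(precision(0.2), 5)
  expect_equal(precision(-0.5), 2)
  expect_identical(precision(0), Inf)
  expect_equal(precision(0, regularize = TRUE), 1e6)
  expect_equal(precision(0.5, regularize = TRUE), 2)
  expect_error(precision(NaN), "finite")
  # identity P(D_r(kappa)) = 1/|kappa - 1|
  for (k in c(0.3, 0.9, 1.4, 2.5)) {
    expect_equal(precision(relative_deviation(k)), 1 / abs(k - 1))
  }
})

test_that("damping regime follows the discriminant and flags oscillation", {
  expect_equal(damping_regime(dynamics_params(1, 2)), "critical")
  expect_equal(damping_regime(dynamics_params(0.75, 2)), "overdamped")
  expect_warning(r <- damping_regime(dynamics_params(4, 2)), "oscillate")
  expect_equal(r, "underdamped")
  expect_error(dynamics_params(-1, 2), "a")
  expect_error(dynamics_params(1, 0), "b")
})

test_that("closed-form solution matches hand-derived branches and the ODE oracle", {
  t <- seq(0, 10, by = 0.1)
  # critically damped: D(t) = (1 + t) e^-t
  tr <- solve_deviation_closed_form(dynamics_params(1, 2), 1, 0, t)
  expect_equal(tr$d_r, (1 + t) * exp(-t), tolerance = 1e-12)
  expect_equal(tr$d_r[t == 1], 2 * exp(-1))
  # overdamped: roots -0.5, -1.5 of r^2 + 2r + 0.75
  tr2 <- solve_deviation_closed_form(dynamics_params(0.75, 2), 1, 0, t)
  expect_equal(tr2$d_r, 1.5 * exp(-0.5 * t) - 0.5 * exp(-1.5 * t),
               tolerance = 1e-12)
  # equilibrium is a fixed point
  tr3 <- solve_deviation_closed_form(dynamics_params(3, 1), 0, 0, t)
  expect_true(all(tr3$d_r == 0))
  # every branch against an independent adaptive integrator
  for (i in seq_len(nrow(damping_grid()))) {
    ab <- damping_grid()[i, ]
    exact <- solve_deviation_closed_form(dynamics_params(ab[1], ab[2]),
                                         0.8, -0.3, t)$d_r
    expect_equal(exact, ode_oracle(ab[1], ab[2], 0.8, -0.3, t),
                 tolerance = 1e-9)
  }
})

test_that("trajectory container derives kappa and precision consistently", {
  tr <- solve_deviation_closed_form(dynamics_params(1, 2), 0.5, 0,
                                    seq(0, 5, 0.5))
  expect_s3_class(tr, "cdt_trajectory")
  expect_equal(tr$kappa, 1 + tr$d_r, tolerance = 1e-15)
  fin <- tr$d_r != 0
  expect_equal(tr$precision[fin], 1 / abs(tr$d_r[fin]))
  expect_warning(gain_trajectory(c(0, 1), c(-1.5, 0)), "kappa")
})

test_that("numerical integrator reproduces the analytic solution in all regimes", {
  t <- seq(0, 10, by = 0.1)
  for (i in seq_len(nrow(damping_grid()))) {
    ab <- damping_grid()[i, ]
    p <- dynamics_params(ab[1], ab[2])
    num <- integrate_deviation(p, 1, 0, t)$d_r
    exact <- solve_deviation_closed_form(p, 1, 0, t)$d_r
    expect_lt(max(abs(num - exact)), 1e-8)
  }
  # zero initial state, no forcing: identically zero
  z <- integrate_deviation(dynamics_params(2, 3), 0, 0, t)
  expect_true(all(z$d_r == 0))
})

test_that("gain dynamics are the deviation dynamics shifted by one", {
  t <- seq(0, 8, by = 0.05)
  g <- gain_dynamics(dynamics_params(1, 2), 2, 0, t)
  expect_equal(g$kappa[t == 1], 1 + 2 * exp(-1), tolerance = 1e-12)
  d <- solve_deviation_closed_form(dynamics_params(1, 2), 1, 0, t)
  expect_lt(max(abs(g$kappa - (1 + d$d_r))), 1e-12)
  # veridical start stays veridical
  flat <- gain_dynamics(dynamics_params(3, 4), 1, 0, t)
  expect_true(all(flat$kappa == 1))
  # change-of-variable equivalence across regimes and initial states
  for (i in seq_len(nrow(damping_grid()))) {
    ab <- damping_grid()[i, ]
    p <- dynamics_params(ab[1], ab[2])
    g2 <- gain_dynamics(p, 1.4, -0.2, t)
    d2 <- solve_deviation_closed_form(p, 0.4, -0.2, t)
    expect_lt(max(abs(g2$kappa - (1 + d2$d_r))), 1e-12)
  }
})

test_that("restoration is asymptotic and non-oscillatory when b^2 >= 4a", {
  for (i in seq_len(nrow(damping_grid()))) {
    ab <- damping_grid()[i, ]
    # horizon from the slowest eigenvalue so |D_r| decays below 1e-3
    disc <- ab[2]^2 - 4 * ab[1]
    rate <- if (disc >= 0) (ab[2] - sqrt(disc)) / 2 else ab[2] / 2
    T_end <- 12 / rate
    tr <- solve_deviation_closed_form(dynamics_params(ab[1], ab[2]), 1, 0,
                                      c(0, T_end))
    expect_lt(abs(tr$d_r[2]), 1e-3)
    if (disc >= 0) {
      # no sign change from rest: monotone-signed decay
      dense <- solve_deviation_closed_form(dynamics_params(ab[1], ab[2]), 1, 0,
                                           seq(0, T_end, length.out = 2000))
      expect_true(all(dense$d_r >= -1e-12))
    }
  }
})

test_that("challenge forcing produces a rise-then-smooth-restore trajectory", {
  t <- seq(0, 20, by = 0.02)
  ch <- challenge_protocol(onset = 2, duration = 4, amplitude = 0.5,
                           shape = "step")
  tr <- integrate_deviation(dynamics_params(1, 2), 0, 0, t, challenge = ch)
  expect_equal(tr$d_r[t <= 2], rep(0, sum(t <= 2)))       # quiet before onset
  i_peak <- which.max(tr$d_r)
  expect_gt(tr$d_r[i_peak], 0.3)                           # driven up
  post <- tr$d_r[t >= t[i_peak] & t >= 6]
  expect_true(all(diff(post) <= 1e-12))                    # monotone decay
  expect_lt(abs(tr$d_r[length(t)]), 1e-3)                  # restored
  # step forcing against the independent oracle
  a <- 1
  u <- function(tt) if (tt >= 2 && tt <= 6) a * 0.5 else 0
  expect_equal(tr$d_r, ode_oracle(1, 2, 0, 0, t, u), tolerance = 1e-7)
  # impulse: velocity kick, then free decay
  chi <- challenge_protocol(onset = 1, amplitude = 1, shape = "impulse")
  tri <- integrate_deviation(dynamics_params(1, 2), 0, 0, t, challenge = chi)
  free <- solve_deviation_closed_form(dynamics_params(1, 2), 0, 1,
                                      t[t >= 1] - 1)
  expect_equal(tri$d_r[t >= 1], free$d_r, tolerance = 1e-8)
  # ramp rises more slowly than step early in the epoch
  chr <- challenge_protocol(onset = 2, duration = 4, amplitude = 0.5,
                            shape = "ramp")
  trr <- integrate_deviation(dynamics_params(1, 2), 0, 0, t, challenge = chr)
  expect_lt(trr$d_r[t == 3], tr$d_r[t == 3])
})

test_that("time grid and state validation reject malformed inputs", {
  p <- dynamics_params(1, 2)
  expect_error(solve_deviation_closed_form(p, 1, 0, c(0, 1, 1)), "increasing")
  expect_error(solve_deviation_closed_form(p, 1, 0, c(-1, 0, 1)), "t >= 0")
  expect_error(solve_deviation_closed_form(p, 1, 0, c(0, NA, 1)), "finite")
  expect_error(integrate_deviation(list(a = 1), 1, 0, 0:3), "cdt_dynamics")
})
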