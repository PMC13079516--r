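# Independent high-accuracy oracle for the restoring ODE: adaptive LSODA
# from deSolve, kept separate from the package's own closed-form and RK4
# solvers.
ode_oracle <- function(a, b, d0, v0, t, u = function(tt) 0) {
  rhs <- function(tt, y, parms) {
    list(c(y[2], -a * y[1] - b * y[2] + u(tt)))
  }
  out <- deSolve::ode(y = c(d0, v0), times = t, func = rhs, parms = NULL,
                      rtol = 1e-12, atol = 1e-12)
  unname(out[, 2])
}

# (a, b) pairs spanning the three damping regimes
damping_grid <- function() {
  rbind(
    c(0.75, 2), c(0.25, 2), c(1, 4),     # overdamped
    c(1, 2), c(4, 4), c(0.25, 1),        # critical
    c(4, 2), c(1, 1), c(9, 2)            # underdamped
  )
}
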