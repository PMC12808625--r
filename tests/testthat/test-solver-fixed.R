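# Fixed-order CF-FF Newton-interpolation integrator.

test_that("fractal weight applied to samples", {
  expect_identical(scale_rhs(7, 0, 0.9), 0)     # singular node zeroed
  expect_identical(scale_rhs(7, 0, 1), 7)       # weight is 1 when beta = 1
  expect_equal(scale_rhs(-3.2, 2.5, 1), -3.2)
  expect_equal(scale_rhs(2, 4, 0.5), 0.5)       # 0.5 * 4^(-0.5) * 2
  expect_error(scale_rhs(1, -1, 0.5), "non-negative")
})

test_that("three-point Newton polynomial", {
  expect_equal(newton_poly3(3.7, 3.7, 3.7), 3.7)        # coefficients sum to 1
  expect_equal(newton_poly3(1, 0, 0), 5 / 12)
  expect_equal(newton_poly3(0, 1, 0), -4 / 3)
  expect_equal(newton_poly3(0, 0, 1), 23 / 12)
  # linear-in-index samples: P_n = n + 1/2, the exact one-step integral of
  # the linear interpolant
  for (n in c(2, 5, 11)) {
    expect_equal(newton_poly3(n - 2, n - 1, n), n + 0.5)
  }
  # exact on quadratics: dt * P equals the true integral over [t_n, t_n+dt]
  dt <- 0.2
  tn <- 1.4
  f <- function(t) 2 - t + 3 * t^2
  P <- newton_poly3(f(tn - 2 * dt), f(tn - dt), f(tn))
  exact <- integrate(f, tn, tn + dt)$value
  expect_equal(dt * P, exact, tolerance = 1e-12)
})

test_that("classical limit reproduces 3-step Adams-Bashforth exactly", {
  p <- gi_parameters()
  f <- function(y) oracle_rhs(y, p, 0.2, 0.1)
  ref <- ab3_reference(f, c(0, 1.5, 1), dt = 0.01, N = 200)
  tr <- gi_simulate(c(0, 1.5, 1), p, gi_gains(0.2, 0.1), alpha = 1, beta = 1,
                    dt = 0.01, T = 2)
  expect_equal(unname(tr$y), ref, tolerance = 1e-13)
})

test_that("integrator matches the printed update rule for fractional orders", {
  p <- gi_parameters()
  f <- function(y) oracle_rhs(y, p, 0.2, 0.1)
  for (cfg in list(c(0.85, 0.9), c(0.98, 1), c(0.9, 0.75))) {
    ref <- cfff_reference(f, c(0, 1.5, 1), alpha = cfg[1], beta = cfg[2],
                          dt = 0.01, N = 100)
    tr <- gi_simulate(c(0, 1.5, 1), p, gi_gains(0.2, 0.1), alpha = cfg[1],
                      beta = cfg[2], dt = 0.01, T = 1)
    # compare over the recorded nodes (a run may truncate on divergence)
    k <- nrow(tr$y)
    expect_equal(unname(tr$y), ref[seq_len(k), ], tolerance = 1e-12,
                 info = paste(cfg, collapse = "/"))
    expect_identical(k, 101L)  # these orders stay finite on this window
  }
})

test_that("observed convergence order on linear decay", {
  p <- zero_params(a1 = 1)
  endpoint_err <- function(dt, bootstrap) {
    tr <- gi_simulate(c(1, 0, 0), p, gains = NULL, alpha = 1, beta = 1,
                      dt = dt, T = 2, bootstrap = bootstrap)
    abs(tr$y[nrow(tr$y), 1] - exp(-2))
  }
  dts <- c(0.04, 0.02, 0.01)
  # printed short-memory start: the one-time O(dt^2) first step caps the
  # observed global order at 2
  e_euler <- vapply(dts, endpoint_err, numeric(1), bootstrap = "euler")
  o_euler <- log2(e_euler[-3] / e_euler[-1])
  expect_true(all(o_euler > 1.8 & o_euler < 2.3))
  # trapezoidal start exposes the third-order multistep core
  e_heun <- vapply(dts, endpoint_err, numeric(1), bootstrap = "heun")
  o_heun <- log2(e_heun[-3] / e_heun[-1])
  expect_true(all(o_heun > 2.6 & o_heun < 3.4))
})

test_that("zero dynamics and equilibrium starts are fixed points", {
  tr <- gi_simulate(c(0.4, -1, 2), zero_params(), gains = NULL,
                    dt = 0.01, T = 1)
  expect_true(all(tr$y[, 1] == 0.4 & tr$y[, 2] == -1 & tr$y[, 3] == 2))
  # starting at a controlled equilibrium triggers the increment stop at once
  eq <- gi_equilibrium(gains = gi_gains(0.2, 0.1), y_init = c(0.5, 1, 1))
  tr2 <- gi_simulate(eq$y, gains = gi_gains(0.2, 0.1), dt = 0.001, T = 10)
  expect_identical(tr2$termination, "converged")
  expect_lt(nrow(tr2$y), 10)
})

test_that("self-convergence under step halving on the controlled system", {
  end_state <- function(dt) {
    tr <- gi_simulate(c(0, 1.5, 1), alpha = 1, beta = 1, dt = dt, T = 10)
    tr$y[nrow(tr$y), ]
  }
  d1 <- max(abs(end_state(0.002) - end_state(0.001)))
  d2 <- max(abs(end_state(0.001) - end_state(0.0005)))
  expect_lt(d2, 1e-4)
  expect_lt(d2, d1)  # still shrinking with the step
})

test_that("blow-up is flagged, truncated and loud", {
  # a11 < 0 makes the logistic term self-reinforcing: finite-time escape
  tr <- gi_simulate(c(0, 2, 0), zero_params(a11 = -10), gains = NULL,
                    dt = 0.001, T = 5)
  expect_identical(tr$termination, "diverged")
  expect_lt(nrow(tr$y), 5001)
  expect_true(all(is.finite(tr$y[seq_len(nrow(tr$y) - 1L), ])))
  expect_identical(sup_norm(tr, from = 0), Inf)
})

test_that("grid validation", {
  expect_error(gi_simulate(c(0, 1.5, 1), dt = 0.3, T = 1), "multiple")
  expect_error(gi_simulate(c(0, 1.5, 1), alpha = 1.2), "alpha")
  expect_error(gi_simulate(c(0, 1.5, 1), dt = -0.1), "positive")
  tr <- gi_simulate(c(0, 1.5, 1), dt = 0.01, T = 1)
  expect_identical(length(tr$time), nrow(tr$y))
  expect_true(all(diff(tr$time) > 0))
})
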