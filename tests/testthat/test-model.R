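# Vector field, Jacobian, and equilibrium solver.

test_that("uncontrolled field reproduces the printed polynomials", {
  # origin: only the constant influx terms survive
  expect_equal(gi_rhs(0, c(0, 0, 0)), c(-0.19, -0.56, 0))
  # zero kinetics: zero field
  expect_equal(gi_rhs(0, c(1.3, -0.7, 2), zero_params()), c(0, 0, 0))
  # term-by-term oracle at a non-trivial state
  expect_equal(gi_rhs(0, c(1, 1, 1)), oracle_rhs(c(1, 1, 1)), tolerance = 1e-13)
})

test_that("field matches the monomial oracle on random states", {
  set.seed(42)
  states <- random_states(300)
  p <- gi_parameters()
  for (i in seq_len(nrow(states))) {
    y <- states[i, ]
    expect_equal(gi_rhs(0, y, p), oracle_rhs(y, p), tolerance = 1e-12)
    expect_equal(gi_rhs(0, y, p, gains = gi_gains(0.2, 0.1)),
                 oracle_rhs(y, p, 0.2, 0.1), tolerance = 1e-12)
  }
})

test_that("control terms are an additive linear feedback", {
  set.seed(7)
  states <- random_states(50)
  p <- gi_parameters()
  for (i in seq_len(nrow(states))) {
    y <- states[i, ]
    base <- gi_rhs(0, y, p)
    # zero gains reduce to the uncontrolled field
    expect_identical(gi_rhs(0, y, p, gains = gi_gains(0, 0)), base)
    # the feedback subtracts (d1 (y1+y2), 0, d3 (y1+y3))
    expect_equal(gi_rhs(0, y, p, gains = gi_gains(0.2, 0.1)),
                 base - c(0.2 * (y[1] + y[2]), 0, 0.1 * (y[1] + y[3])))
    # linear in the gains (absolute bound: the control terms may vanish)
    g1 <- gi_rhs(0, y, p, gains = gi_gains(0.1, 0.05)) - base
    g2 <- gi_rhs(0, y, p, gains = gi_gains(0.3, 0.15)) - base
    expect_lt(max(abs(3 * g1 - g2)), 1e-12)
  }
})

test_that("the a8 sign convention switch flips only the bilinear term", {
  y <- c(0.8, -1.2, 0.5)
  neg <- gi_rhs(0, y, a8_sign = "negative")
  pos <- gi_rhs(0, y, a8_sign = "positive")
  expect_equal(pos - neg, c(0, 2 * 0.22 * y[1] * y[2], 0))
})

test_that("invalid states and gains are rejected with informative errors", {
  expect_error(gi_rhs(0, c(1, NaN, 0)), "y2")
  expect_error(gi_rhs(0, c(Inf, 0, 0)), "y1")
  expect_error(gi_gains(-0.1, 0.2), "non-negative")
  expect_error(gi_parameters(a22 = 1), "unknown parameter")
})

test_that("analytic Jacobian agrees with central differences", {
  p <- gi_parameters()
  g <- gi_gains(0.2, 0.1)
  f <- function(y) gi_rhs(0, y, p, gains = g)
  J <- gi_jacobian(y = c(0.5, 1, 1), params = p, gains = g)
  expect_equal(J, fd_jacobian(f, c(0.5, 1, 1)), tolerance = 1e-6)
  set.seed(11)
  for (y in asplit(random_states(25), 1)) {
    expect_equal(gi_jacobian(y = y, params = p, gains = g),
                 fd_jacobian(f, as.numeric(y)), tolerance = 1e-6)
  }
  # entry (1,2): a2 y1 + 2 a3 y2 + 3 a4 y2^2 - d1
  y <- c(1, 1, 1)
  expect_equal(gi_jacobian(y = y, gains = g)[1, 2],
               0.10 * 1 + 2 * 1.09 * 1 + 3 * (-1.08) * 1 - 0.2)
  # zero kinetics and gains: zero matrix
  expect_equal(gi_jacobian(y = c(1, 2, 3), params = zero_params()),
               matrix(0, 3, 3))
})

test_that("equilibrium solver finds verified roots", {
  # pure linear decay in y1 (rank-deficient Jacobian): the decaying
  # direction is driven to zero, the frozen directions stay put
  eq <- gi_equilibrium(zero_params(a1 = 1), y_init = c(0.5, 0, 0))
  expect_true(eq$converged)
  expect_equal(eq$y, c(0, 0, 0), tolerance = 1e-9)
  # full linear decay: origin is the unique equilibrium from anywhere
  eqf <- gi_equilibrium(zero_params(a1 = 1, a11 = -1, a18 = 1),
                        y_init = c(0.5, 0.3, -0.2))
  expect_true(eqf$converged)
  expect_equal(eqf$y, c(0, 0, 0), tolerance = 1e-9)
  # reference parameters, uncontrolled: residual check is definitional
  eq2 <- gi_equilibrium(y_init = c(0.5, 1, 1))
  expect_true(eq2$converged)
  expect_lt(max(abs(gi_rhs(0, eq2$y))), 1e-10)
  # controlled root satisfies the controlled field
  eq3 <- gi_equilibrium(gains = gi_gains(0.2, 0.1), y_init = c(0.5, 1, 1))
  expect_true(eq3$converged)
  expect_lt(max(abs(gi_rhs(0, eq3$y, gains = gi_gains(0.2, 0.1)))), 1e-10)
  expect_error(gi_equilibrium(y_init = c(NA, 0, 0)))
})
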