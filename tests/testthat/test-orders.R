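# CF normalization, fractal-exponent profiles, kernel coefficients, and the
# reference fractal-fractional integral.

test_that("normalization constant hits both unit endpoints and the Gamma form", {
  expect_identical(cf_normalization(0), 1)
  expect_identical(cf_normalization(1), 1)
  expect_equal(cf_normalization(0.85), 1 - 0.85 + 0.85 / gamma(0.85))
  expect_error(cf_normalization(1.2), "\\[0, 1\\]")
  expect_error(cf_normalization(-0.1), "\\[0, 1\\]")
})

test_that("shipped profiles evaluate correctly and stay in (0, 1]", {
  expect_equal(round(beta_eval("cos_fast", 1), 5), 0.96081)
  expect_equal(beta_eval(1, c(0, 3, 77)), c(1, 1, 1))
  expect_equal(beta_eval("cos_slow", 0), 1)     # cos(0) = 1, clipped boundary
  tt <- seq(0, 120, by = 0.25)
  for (nm in c("cos_slow", "cos_fast", "tanh1p", "sigmoid")) {
    v <- beta_eval(nm, tt)
    expect_true(all(v > 0 & v <= 1), info = nm)
  }
  expect_error(beta_eval("cubic_spline", 1), "unknown beta profile")
  expect_error(beta_eval("cos_fast", -1), "non-negative")
  expect_equal(beta_eval("const:0.9", 5), 0.9)
})

test_that("profile derivatives: analytic values and forward-difference consistency", {
  expect_equal(round(beta_deriv("cos_fast", 1), 5), -0.01683)
  expect_equal(beta_deriv(0.97, 2.5), 0)
  expect_equal(beta_deriv(0.97, 2.5, dt = 0.01, mode = "forward_difference"), 0)
  # forward difference converges to the analytic slope at rate O(dt)
  for (nm in c("cos_fast", "sigmoid")) {
    errs <- vapply(c(1e-2, 1e-3, 1e-4), function(dt) {
      abs(beta_deriv(nm, 2, dt = dt, mode = "forward_difference") -
            beta_deriv(nm, 2))
    }, numeric(1))
    rates <- log10(errs[-3] / errs[-1])
    expect_true(all(rates > 0.8 & rates < 1.2), info = nm)
  }
})

test_that("growth rate of t^beta(t) matches the chain rule and differentiation", {
  # constant exponent degenerates to beta * t^(beta - 1)
  tt <- 10^seq(-2, 2, length.out = 9)
  expect_equal(tbeta_rate(beta_profile(0.5), tt), 0.5 * tt^(-0.5))
  # ln 1 = 0: the rate at t = 1 is just beta(1)
  for (nm in c("cos_slow", "cos_fast", "sigmoid")) {
    expect_equal(tbeta_rate(nm, 1), beta_eval(nm, 1), info = nm)
  }
  # central difference of t^beta(t) at t = 2.5
  h <- 1e-6
  for (nm in c("cos_slow", "cos_fast", "tanh1p", "sigmoid")) {
    num <- ((2.5 + h)^beta_eval(nm, 2.5 + h) -
              (2.5 - h)^beta_eval(nm, 2.5 - h)) / (2 * h)
    expect_equal(tbeta_rate(nm, 2.5), num, tolerance = 1e-6, info = nm)
  }
  expect_error(tbeta_rate("cos_fast", 0), "strictly positive")
})

test_that("variable-order kernel coefficient kappa", {
  expect_equal(round(vo_kappa("cos_fast", 1, 0.1), 5), 0.96081)
  # constant exponent: reduces to the fixed-order scale factor on a log grid
  tt <- 10^seq(-2, 2, length.out = 9)
  for (t_n in tt) {
    expect_equal(vo_kappa(0.85, t_n, 0.01), 0.85 * t_n^(-0.15),
                 tolerance = 1e-13)
  }
  # at t = 1 the log term vanishes for any profile
  for (nm in c("cos_slow", "tanh1p", "sigmoid")) {
    expect_equal(vo_kappa(nm, 1, 0.05), beta_eval(nm, 1), info = nm)
  }
  expect_error(vo_kappa("cos_fast", 0, 0.1), "strictly positive")
})

test_that("auxiliary term g equals the kernel-weighted sample", {
  g <- vo_gterm("cos_fast", 1, 0.1, h_val = 2.5)
  expect_equal(g, 2.40203, tolerance = 1e-4)   # printed value, rounded twice
  expect_equal(g, 2.5 * vo_kappa("cos_fast", 1, 0.1), tolerance = 1e-14)
  expect_identical(vo_gterm("cos_fast", 3, 0.1, h_val = 0), 0)
  # g = h * kappa identically under the forward-difference slope
  for (t_n in c(0.3, 1.7, 12)) {
    for (dt in c(0.1, 0.001)) {
      expect_equal(vo_gterm("sigmoid", t_n, dt, h_val = -1.4),
                   -1.4 * vo_kappa("sigmoid", t_n, dt), tolerance = 1e-13)
    }
  }
})

test_that("fractal-fractional integral against a quadrature oracle", {
  tt <- seq(0, 1, length.out = 2001)
  expect_identical(cf_ff_integral(rep(0, 2001), 0.5, 0.5, 1), 0)
  # f = 1, alpha = beta = 0.5: weighted integral + local term, oracle by
  # adaptive quadrature of the singular weight
  val <- cf_ff_integral(rep(1, 2001), 0.5, 0.5, 1)
  I <- stats::integrate(function(mu) mu^(-0.5), 0, 1)$value
  bh <- 1 - 0.5 + 0.5 / gamma(0.5)
  expect_equal(val, 0.25 * I / bh + 0.25 / bh, tolerance = 1e-4)
  # smooth non-constant integrand
  f <- sin(pi * tt) + 1
  val2 <- cf_ff_integral(f, 0.7, 0.9, 1)
  I2 <- stats::integrate(function(mu) mu^(-0.3) * (sin(pi * mu) + 1), 0, 1)$value
  bh2 <- 1 - 0.7 + 0.7 / gamma(0.7)
  expect_equal(val2, 0.7 * 0.9 / bh2 * I2 + 0.9 * 0.3 / bh2 * f[2001],
               tolerance = 1e-4)
  # near the classical limit the local term's weight (1 - alpha) vanishes
  val3 <- cf_ff_integral(f, 1 - 1e-9, 1, 1)
  expect_equal(val3, stats::integrate(function(mu) sin(pi * mu) + 1, 0, 1)$value,
               tolerance = 1e-3)
  expect_error(cf_ff_integral(numeric(0), 0.5, 0.5, 1), "two samples")
})
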