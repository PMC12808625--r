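# Independent oracles used across the suite.  They share no code with the
# package internals: the vector field is rebuilt from an explicit monomial
# table, the Jacobian from central differences, and the reference integrators
# are written from the textbook formulas.

# parameters with every kinetic constant zero except the named overrides
zero_params <- function(...) {
  z <- as.list(stats::setNames(rep(0, 21), paste0("a", 1:21)))
  do.call(gi_parameters, utils::modifyList(z, list(...)))
}

# monomial table of the three equations: sign * a_idx * y1^p1 y2^p2 y3^p3
.gi_terms <- list(
  eq1 = rbind(
    c(-1,  1, 1, 0, 0), c( 1,  2, 1, 1, 0), c( 1,  3, 0, 2, 0),
    c( 1,  4, 0, 3, 0), c( 1,  5, 0, 0, 1), c( 1,  6, 0, 0, 2),
    c( 1,  7, 0, 0, 3), c( 1, 20, 0, 0, 0)),
  eq2 = rbind(
    c(-1,  8, 1, 1, 0), c(-1,  9, 2, 0, 0), c(-1, 10, 3, 0, 0),
    c( 1, 11, 0, 1, 0), c(-1, 11, 0, 2, 0), c(-1, 12, 0, 0, 1),
    c(-1, 13, 0, 0, 2), c(-1, 14, 0, 0, 3), c( 1, 21, 0, 0, 0)),
  eq3 = rbind(
    c( 1, 15, 0, 1, 0), c( 1, 16, 0, 2, 0), c( 1, 17, 0, 3, 0),
    c(-1, 18, 0, 0, 1), c(-1, 19, 0, 1, 1))
)

# term-by-term evaluation of the controlled field
oracle_rhs <- function(y, params = gi_parameters(), d1 = 0, d3 = 0) {
  a <- unclass(params)
  val <- vapply(.gi_terms, function(tab) {
    sum(tab[, 1] * a[tab[, 2]] *
          y[1]^tab[, 3] * y[2]^tab[, 4] * y[3]^tab[, 5])
  }, numeric(1))
  unname(val - c(d1 * (y[1] + y[2]), 0, d3 * (y[1] + y[3])))
}

# central-difference Jacobian of any vector field
fd_jacobian <- function(f, y, h = 1e-6) {
  d <- length(y)
  J <- matrix(NA_real_, d, d)
  for (j in seq_len(d)) {
    e <- numeric(d); e[j] <- h
    J[, j] <- (f(y + e) - f(y - e)) / (2 * h)
  }
  J
}

# textbook Adams-Bashforth reference with forward-Euler then AB2 start,
# written independently of the package's stepper
ab3_reference <- function(f, y0, dt, N) {
  y <- y0
  out <- matrix(NA_real_, N + 1L, length(y0))
  out[1L, ] <- y0
  f1 <- f2 <- NULL
  for (n in 0:(N - 1L)) {
    f0 <- f(y)
    y <- if (n == 0L) y + dt * f0
         else if (n == 1L) y + dt * (3 / 2 * f0 - 1 / 2 * f1)
         else y + dt * (23 * f0 - 16 * f1 + 5 * f2) / 12
    out[n + 2L, ] <- y
    f2 <- f1; f1 <- f0
  }
  out
}

# reference fixed-order CF-FF scheme written straight from the printed
# update rule (scalar weights, explicit loops), for cross-checking the
# packaged integrator on arbitrary alpha, beta
cfff_reference <- function(f, y0, alpha, beta, dt, N) {
  Bh <- 1 - alpha + alpha / gamma(alpha)
  tgrid <- (0:N) * dt
  y <- y0
  out <- matrix(NA_real_, N + 1L, length(y0))
  out[1L, ] <- y0
  Um1 <- Um2 <- rep(0, length(y0))
  for (n in 0:(N - 1L)) {
    w <- if (tgrid[n + 1L] == 0) (if (beta < 1) 0 else beta)
         else beta * tgrid[n + 1L]^(beta - 1)
    U <- w * f(y)
    P <- if (n == 0L) U
         else if (n == 1L) 3 / 2 * U - 1 / 2 * Um1
         else 23 / 12 * U - 4 / 3 * Um1 + 5 / 12 * Um2
    y <- y + (1 - alpha) / Bh * (U - Um1) + alpha / Bh * P * dt
    out[n + 2L, ] <- y
    Um2 <- Um1; Um1 <- U
  }
  out
}

# random finite states drawn once per call under the caller's seed
random_states <- function(n, scale = 2) {
  matrix(stats::runif(3 * n, -scale, scale), ncol = 3)
}
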