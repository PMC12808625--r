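# Computable stability and validation quantities: Lipschitz contraction
# constants, Hyers-Ulam stability constants, Benettin Lyapunov spectra and
# normalized root-mean-square error.

#' Lipschitz constants and contraction check
#'
#' Evaluates the per-equation Lipschitz constants of the glucose-insulin
#' field under sup-norm state bounds, exactly as the stability analysis
#' writes them:
#' `gamma1 = a1 + a2 K_y3`, `gamma2 = a8 K_y1 + a11 (1 + 2 K_y2)`,
#' `gamma3 = a18 + a19 K_y2`, with `M = max(gamma_i)` and the contraction
#' flag `0 <= M < 1`.  The formulas are applied verbatim — no absolute values
#' are inserted, so `gamma3` is negative for the reference parameters
#' (`a18`, `a19 < 0`) and the contraction condition fails for them; the
#' report states what the formulas give.  (Note `gamma1` couples to the bound
#' of `y3` as written, although the `y1` equation's bilinear term involves
#' `y2`.)
#'
#' @param params model parameters.
#' @param bounds state bounds, see [gi_state_bounds()].
#' @return A list of class `"lipschitz_report"` with `gamma1..gamma3`, `M`,
#'   `contraction`.
#' @examples
#' lipschitz_constants(gi_parameters(), gi_state_bounds(0, 0, 0))
#' @export
lipschitz_constants <- function(params = gi_parameters(),
                                bounds = gi_state_bounds()) {
  a <- as_params(params)
  b <- unclass(bounds)
  if (length(b) != 3L || any(b < 0)) {
    stop("`bounds` must be three non-negative values", call. = FALSE)
  }
  g1 <- a[["a1"]] + a[["a2"]] * b[[3L]]
  g2 <- a[["a8"]] * b[[1L]] + a[["a11"]] * (1 + 2 * b[[2L]])
  g3 <- a[["a18"]] + a[["a19"]] * b[[2L]]
  M <- max(g1, g2, g3)
  structure(list(gamma1 = g1, gamma2 = g2, gamma3 = g3, M = M,
                 contraction = (M >= 0 && M < 1)),
            class = "lipschitz_report")
}

#' @export
print.lipschitz_report <- function(x, ...) {
  cat(sprintf("Lipschitz constants: gamma1 = %g, gamma2 = %g, gamma3 = %g\n",
              x$gamma1, x$gamma2, x$gamma3))
  cat(sprintf("M = max(gamma) = %g; contraction (0 <= M < 1): %s\n",
              x$M, x$contraction))
  invisible(x)
}

#' Hyers-Ulam stability constants
#'
#' The common constant of the three state equations,
#' `lambda = (beta (1 - alpha) t^(beta-1) + alpha beta T^(beta-1)) / B(alpha)`,
#' bounding the deviation of an approximate solution of the CF-FF integral
#' equation from an exact one (per unit defect).  Collapses to
#' `1 / B(alpha)` at `beta = 1` and to `beta T^(beta-1)` at `alpha = 1`.
#'
#' @param alpha fractional order in `(0, 1]`.
#' @param beta fractal exponent in `(0, 1]`.
#' @param t evaluation time, `> 0` (required for `beta < 1`).
#' @param T horizon, `> 0`.
#' @return A list of class `"hyers_ulam_report"` with `lambda1..lambda3`
#'   (all equal) and the inputs.
#' @examples
#' hyers_ulam_constants(0.85, 0.96, t = 1, T = 120)
#' @export
hyers_ulam_constants <- function(alpha, beta, t, T) {
  if (alpha <= 0 || alpha > 1 || beta <= 0 || beta > 1) {
    stop("`alpha` and `beta` must lie in (0, 1]", call. = FALSE)
  }
  if ((t <= 0 || T <= 0) && beta < 1) {
    stop("`t` and `T` must be positive (t^(beta-1) is singular at 0)",
         call. = FALSE)
  }
  lam <- (beta * (1 - alpha) * t^(beta - 1) +
            alpha * beta * T^(beta - 1)) / cf_normalization(alpha)
  structure(list(lambda1 = lam, lambda2 = lam, lambda3 = lam,
                 alpha = alpha, beta = beta, t = t, T = T),
            class = "hyers_ulam_report")
}

#' @export
print.hyers_ulam_report <- function(x, ...) {
  cat(sprintf("Hyers-Ulam constant lambda = %g (alpha = %g, beta = %g, t = %g, T = %g)\n",
              x$lambda1, x$alpha, x$beta, x$t, x$T))
  invisible(x)
}

#' Lyapunov spectrum by Benettin QR re-orthonormalization
#'
#' Propagates a full tangent frame along a supplied base trajectory with the
#' supplied Jacobian, re-orthonormalizing by QR every `renorm_every` steps and
#' averaging the log stretch factors after discarding an initial transient.
#'
#' @param deriv function `(t, y) -> dy` for the base flow.
#' @param jac function `(t, y) -> 3 x 3` (or `d x d`) Jacobian.
#' @param y0 initial state.
#' @param dt time step.
#' @param T horizon.
#' @param renorm_every QR re-orthonormalization interval in steps (default 10).
#' @param transient_frac fraction of the horizon discarded before averaging
#'   (default 0.2).
#' @param traj optional precomputed base trajectory: a matrix of states on the
#'   uniform grid (rows = nodes).  When given, `deriv` is not used for the
#'   base and the tangents are advanced along it.
#' @return A list of class `"lyapunov_report"`: `exponents` (sorted
#'   decreasing), `horizon`, `renorm_every`, `transient_frac`.
#' @examples
#' rep <- benettin_lyapunov(function(t, y) -c(1, 2, 3) * y,
#'                          function(t, y) diag(c(-1, -2, -3)),
#'                          y0 = c(1, 1, 1), dt = 0.01, T = 20)
#' rep$exponents   # close to (-1, -2, -3)
#' @export
benettin_lyapunov <- function(deriv, jac, y0, dt = 0.001, T = 100,
                              renorm_every = 10L, transient_frac = 0.2,
                              traj = NULL) {
  d <- length(y0)
  N <- round(T / dt)
  have_traj <- !is.null(traj)
  if (have_traj) {
    traj <- as.matrix(traj)
    if (nrow(traj) < N + 1L) {
      # truncated (diverged) base: shorten the horizon to what exists
      N <- nrow(traj) - 1L
      if (N < 2L) stop("base trajectory too short for exponent estimation",
                       call. = FALSE)
    }
  }
  n0 <- round(transient_frac * N)
  Q <- diag(d)
  acc <- numeric(d)
  t_acc <- 0
  y <- as.numeric(y0)
  f_nm1 <- NULL
  for (n in 0:(N - 1L)) {
    t_n <- n * dt
    y_n <- if (have_traj) traj[n + 1L, ] else y
    J <- jac(t_n, y_n)
    Q <- Q + dt * (J %*% Q)
    if (!all(is.finite(Q))) {
      stop("tangent propagation diverged at t = ", t_n, call. = FALSE)
    }
    if ((n + 1L) %% renorm_every == 0L) {
      qrd <- qr(Q)
      R <- qr.R(qrd)
      sg <- sign(diag(R)); sg[sg == 0] <- 1
      Q <- qr.Q(qrd) %*% diag(sg, d)
      if (n >= n0) {
        acc <- acc + log(abs(diag(R)))
        t_acc <- t_acc + renorm_every * dt
      }
    }
    if (!have_traj) {
      # two-step Adams-Bashforth base integration
      f_n <- deriv(t_n, y)
      y <- if (is.null(f_nm1)) y + dt * f_n
           else y + dt * (1.5 * f_n - 0.5 * f_nm1)
      f_nm1 <- f_n
    }
  }
  if (t_acc == 0) stop("horizon too short: no post-transient renormalization",
                       call. = FALSE)
  structure(list(exponents = sort(acc / t_acc, decreasing = TRUE),
                 horizon = N * dt, renorm_every = renorm_every,
                 transient_frac = transient_frac),
            class = "lyapunov_report")
}

#' @export
print.lyapunov_report <- function(x, ...) {
  cat("Lyapunov exponents:",
      paste(format(x$exponents, digits = 5), collapse = ", "), "\n")
  cat(sprintf("  (horizon %g, QR every %d steps, transient %g%%)\n",
              x$horizon, x$renorm_every, 100 * x$transient_frac))
  invisible(x)
}

#' Lyapunov spectrum of the glucose-insulin system
#'
#' Runs [gi_simulate()] to obtain the CF-FF base trajectory, then applies
#' [benettin_lyapunov()] with the analytic Jacobian of the controlled field
#' along it.  If the base run diverges, the exponents are estimated on the
#' finite part and the report is flagged.
#'
#' @inheritParams gi_simulate
#' @param renorm_every,transient_frac see [benettin_lyapunov()].
#' @return A `"lyapunov_report"` with an extra `termination` field from the
#'   base run.
#' @examples
#' rep <- gi_lyapunov(c(0, 1.5, 1), gains = gi_gains(0.2, 0.1),
#'                    dt = 0.01, T = 20)
#' @export
gi_lyapunov <- function(y0 = c(0, 1.5, 1), params = gi_parameters(),
                        gains = gi_gains(0.2, 0.1), alpha = 1, beta = 1,
                        dt = 0.001, T = 100, renorm_every = 10L,
                        transient_frac = 0.2,
                        a8_sign = c("negative", "positive")) {
  a <- as_params(params)
  g <- as_gains(gains)
  s8 <- a8_sign_value(a8_sign)
  base <- gi_simulate(y0, params, gains, alpha = alpha, beta = beta,
                      dt = dt, T = T, stop_delta = 0, a8_sign = a8_sign)
  rep <- benettin_lyapunov(
    deriv = NULL,
    jac = function(t, y) .jac3(y[1L], y[2L], y[3L], a, g$d1, g$d3, s8),
    y0 = y0, dt = dt, T = T, renorm_every = renorm_every,
    transient_frac = transient_frac, traj = base$y
  )
  rep$termination <- base$termination
  rep
}

#' Normalized root-mean-square error between two series
#'
#' `sqrt(mean((ref - model)^2)) / (max(ref) - min(ref))`.  The reference
#' series must not be constant.
#'
#' @param g_ref reference series.
#' @param g_model model series of the same length.
#' @return The NRMSE, a non-negative scalar.
#' @examples
#' nrmse(c(0, 1), c(1, 0))   # 1
#' @export
nrmse <- function(g_ref, g_model) {
  if (length(g_ref) != length(g_model)) {
    stop("series must have equal length", call. = FALSE)
  }
  rng <- max(g_ref) - min(g_ref)
  if (rng == 0) {
    stop("reference series is constant: NRMSE undefined (zero range)",
         call. = FALSE)
  }
  sqrt(mean((g_ref - g_model)^2)) / rng
}
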