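# Variable-order CF-FF Newton-interpolation integrator.
#
# For a time-varying fractal exponent the scaled sample becomes
#   G_n = kappa_n * h_n,   kappa_n = t_n^beta(t_n) * (slope_n log t_n + beta(t_n)/t_n)
# with the forward-difference slope slope_n = (beta(t_n + dt) - beta(t_n))/dt,
# and per component the two-point update
#   u_{n+1} = u_n + (1-alpha)/B(alpha) * (kappa_n h_n - kappa_{n-1} h_{n-1})
#                 + alpha/B(alpha) * (3/2 g_n - 1/2 g_{n-1}) * dt
# where g_n = kappa_n h_n when the forward-difference slope is used.  The
# printed one-line update is typographically ambiguous; this memory-difference
# parse mirrors the fixed scheme's (U_n - U_{n-1}) structure and is its exact
# constant-beta generalization.  Node 0 (t = 0, where kappa is undefined) uses
# the fixed-order bootstrap with the short-memory convention.

#' Two-point quadrature of the local variable-order integral
#'
#' `(3/2) g_n dt - (1/2) g_{n-1} dt`, exact for linear extrapolants of the
#' integrand.
#'
#' @param g_n,g_nm1 consecutive weighted samples.
#' @param dt time step.
#' @return The quadrature value.
#' @examples
#' vo_local_integral(2.40203, 2.40203, 0.1)   # 0.240203
#' @export
vo_local_integral <- function(g_n, g_nm1, dt) {
  (1.5 * g_n - 0.5 * g_nm1) * dt
}

#' One variable-order CF-FF update step
#'
#' Advances a scalar component by the two-point variable-order rule.
#'
#' @param u_n current value.
#' @param h_nm1,h_n right-hand-side samples at the previous and current node.
#' @param kappa_nm1,kappa_n kernel coefficients ([vo_kappa()]) at the two nodes.
#' @param g_nm1,g_n weighted samples ([vo_gterm()]) at the two nodes.
#' @param alpha fractional order in `(0, 1]`.
#' @param dt time step.
#' @return The updated value `u_{n+1}`.
#' @examples
#' vo_step(1, h_nm1 = 0, h_n = 0, kappa_nm1 = 1, kappa_n = 1,
#'         g_nm1 = 0, g_n = 0, alpha = 0.9, dt = 0.01)   # stays 1
#' @export
vo_step <- function(u_n, h_nm1, h_n, kappa_nm1, kappa_n, g_nm1, g_n,
                    alpha, dt) {
  terms <- c(kappa_n, kappa_nm1, g_n, g_nm1, h_n, h_nm1)
  if (any(!is.finite(terms))) {
    stop("non-finite kernel term in variable-order step", call. = FALSE)
  }
  bh <- cf_normalization(alpha)
  u_n + (1 - alpha) / bh * (kappa_n * h_n - kappa_nm1 * h_nm1) +
    alpha / bh * vo_local_integral(g_n, g_nm1, dt)
}

# core variable-order loop; profile is a beta_profile
.simulate_vo <- function(y0, a, d1, d3, s8, alpha, profile, dt, N,
                         stop_delta, blowup) {
  tgrid <- (0:N) * dt
  bv <- beta_eval(profile, tgrid)
  slope <- (beta_eval(profile, tgrid + dt) - bv) / dt
  kfac <- tgrid^bv * (slope * log(tgrid) + bv / tgrid)  # NaN at node 0, unused
  bh <- cf_normalization(alpha)
  c_mem <- (1 - alpha) / bh
  c_qud <- alpha / bh * dt
  out <- matrix(NA_real_, N + 1L, 3L)
  out[1L, ] <- y0
  y1 <- y0[1L]; y2 <- y0[2L]; y3 <- y0[3L]
  # node 0: fixed-order bootstrap with beta(0) and the short-memory convention
  b0 <- bv[1L]
  G_prev <- (if (b0 < 1) 0 else b0) * .rhs3(y1, y2, y3, a, d1, d3, s8)
  dy <- c_mem * G_prev + c_qud * G_prev
  y1 <- y1 + dy[1L]; y2 <- y2 + dy[2L]; y3 <- y3 + dy[3L]
  out[2L, ] <- c(y1, y2, y3)
  termination <- "horizon"
  n_last <- N + 1L
  if (N >= 2L) {
    for (n in 1:(N - 1L)) {
      G <- kfac[n + 1L] * .rhs3(y1, y2, y3, a, d1, d3, s8)
      dy <- c_mem * (G - G_prev) + c_qud * (1.5 * G - 0.5 * G_prev)
      y1 <- y1 + dy[1L]; y2 <- y2 + dy[2L]; y3 <- y3 + dy[3L]
      out[n + 2L, ] <- c(y1, y2, y3)
      G_prev <- G
      if (!all(is.finite(c(y1, y2, y3))) ||
          max(abs(c(y1, y2, y3))) > blowup) {
        termination <- "diverged"; n_last <- n + 2L; break
      }
      if (max(abs(dy)) < stop_delta) {
        termination <- "converged"; n_last <- n + 2L; break
      }
    }
  }
  list(time = tgrid[seq_len(n_last)],
       y = out[seq_len(n_last), , drop = FALSE],
       termination = termination)
}

#' Simulate the glucose-insulin system under a CF-FF operator
#'
#' Integrates the (controlled) glucose-insulin system on a uniform grid with
#' the Caputo-Fabrizio fractal-fractional Newton-interpolation scheme.  A
#' constant fractal exponent selects the fixed-order integrator (three-point
#' Newton polynomial by default); a time-varying profile selects the
#' variable-order integrator driven by the kernel coefficients
#' [vo_kappa()] / [vo_gterm()].
#'
#' The run stops at the horizon `T`, when the sup-norm step increment falls
#' below `stop_delta` (termination `"converged"`), or when a state exceeds
#' `blowup` in magnitude or turns non-finite (termination `"diverged"`, with
#' the trajectory truncated at the last recorded node).
#'
#' @param y0 initial state `c(y1, y2, y3)`.
#' @param params model parameters ([gi_parameters()]).
#' @param gains feedback gains ([gi_gains()]), or `NULL` for the uncontrolled
#'   system.
#' @param alpha fractional order in `(0, 1]`.
#' @param beta fractal exponent: a constant in `(0, 1]`, a profile name, or a
#'   [beta_profile()].
#' @param dt time step (default `0.001`).
#' @param T horizon (default `120`).
#' @param scheme `"auto"` (fixed for constant `beta`, variable otherwise),
#'   `"fixed"`, or `"variable"`.
#' @param newton_order quadrature order of the fixed scheme for `n >= 2`:
#'   `3` (three-point, default) or `2` (two-point at every step, the exact
#'   constant-exponent twin of the variable-order scheme).
#' @param bootstrap first-step rule of the fixed scheme: `"euler"` (the
#'   short-memory start, default) or `"heun"` (a two-evaluation trapezoidal
#'   start matching the multistep core's local order, for convergence
#'   studies).
#' @param stop_delta sup-norm stopping threshold (default `1e-8`).
#' @param blowup divergence threshold on the state magnitude (default `1e6`).
#' @param a8_sign sign convention for the `a8` cross term, see [gi_rhs()].
#' @return A `gi_trajectory` object.
#' @examples
#' tr <- gi_simulate(c(0, 1.5, 1), alpha = 1, beta = 1, dt = 0.01, T = 5)
#' summary(tr, late_from = 1)
#' @export
gi_simulate <- function(y0 = c(0, 1.5, 1), params = gi_parameters(),
                        gains = gi_gains(0.2, 0.1), alpha = 1, beta = 1,
                        dt = 0.001, T = 120,
                        scheme = c("auto", "fixed", "variable"),
                        newton_order = 3L, stop_delta = 1e-8, blowup = 1e6,
                        bootstrap = c("euler", "heun"),
                        a8_sign = c("negative", "positive")) {
  bootstrap <- match.arg(bootstrap)
  y0 <- check_state(y0)
  a <- as_params(params)
  g <- as_gains(gains)
  s8 <- a8_sign_value(a8_sign)
  scheme <- match.arg(scheme)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("`alpha` must lie in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(dt) || dt <= 0 || !is.numeric(T) || T <= 0) {
    stop("`dt` and `T` must be positive", call. = FALSE)
  }
  N <- round(T / dt)
  if (abs(N * dt - T) > 1e-9 * max(1, T)) {
    stop("`T` must be an integer multiple of `dt`", call. = FALSE)
  }
  if (!newton_order %in% c(2L, 3L)) {
    stop("`newton_order` must be 2 or 3", call. = FALSE)
  }
  profile <- beta_profile(beta)
  constant <- !is.na(profile$constant)
  if (scheme == "auto") scheme <- if (constant) "fixed" else "variable"
  if (scheme == "fixed" && !constant) {
    stop("the fixed-order scheme needs a constant fractal exponent; ",
         "use scheme = \"variable\"", call. = FALSE)
  }
  res <- if (scheme == "fixed") {
    .simulate_fixed(y0, a, g$d1, g$d3, s8, alpha, profile$constant, dt, N,
                    as.integer(newton_order), stop_delta, blowup, bootstrap)
  } else {
    .simulate_vo(y0, a, g$d1, g$d3, s8, alpha, profile, dt, N,
                 stop_delta, blowup)
  }
  new_trajectory(res$time, res$y, scheme, alpha, profile$label,
                 list(d1 = g$d1, d3 = g$d3), dt, T, res$termination,
                 if (s8 < 0) "negative" else "positive")
}
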