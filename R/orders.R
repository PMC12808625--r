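# Caputo-Fabrizio fractal-fractional operator ingredients: the normalization
# constant, fractal-exponent profiles beta(t) with their derivatives, the
# d/dt t^beta(t) identity, the variable-order kernel coefficients, and the
# exponential-kernel fractal-fractional integral as a reference quadrature.

# profiles are clipped into [BETA_MIN, 1] so that t^(beta-1) stays finite
BETA_MIN <- 1e-3

#' Caputo-Fabrizio normalization constant
#'
#' The exponential-kernel normalization `B(alpha) = 1 - alpha + alpha / Gamma(alpha)`,
#' equal to 1 at both endpoints `alpha = 0` (limit, since
#' `alpha / Gamma(alpha) -> 0`) and `alpha = 1`.
#'
#' @param alpha fractional order in \[0, 1\].
#' @return The normalization value, a positive scalar.
#' @examples
#' cf_normalization(1)     # exactly 1
#' cf_normalization(0.85)
#' @export
cf_normalization <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0 || alpha > 1) {
    stop("`alpha` must lie in [0, 1]", call. = FALSE)
  }
  if (alpha == 0) return(1)  # continuous limit: alpha/Gamma(alpha) -> 0
  1 - alpha + alpha / gamma(alpha)
}

#' Fractal-exponent profile beta(t)
#'
#' Constructs a fractal-exponent law.  Accepts a constant in `(0, 1]`, one of
#' the named profiles, a string `"const:<value>"`, or a user function of time
#' (with an optional analytic derivative).  Named profiles:
#' \describe{
#'   \item{`cos_slow`}{`0.97 + 0.03 cos(t / 10)` — slow circadian-type oscillation}
#'   \item{`cos_fast`}{`0.95 + 0.02 cos(t)` — fast oscillation}
#'   \item{`tanh1p`}{`tanh(1 + t)` — gradual memory accumulation}
#'   \item{`sigmoid`}{`1 / (1 + exp(-t))` — sigmoidal adaptation}
#' }
#' Evaluations are clipped to `[1e-3, 1]` so the weight `t^(beta - 1)` stays
#' well defined; the shipped profiles are unaffected by the lower clip on
#' `t >= 0`.
#'
#' @param x a number, profile name, or function `function(t) ...`.
#' @param deriv optional analytic derivative function for a custom profile.
#' @return An object of class `"beta_profile"` with fields `label`, `fun`,
#'   `dfun` (analytic derivative or `NULL`), `constant` (the value, or `NA`).
#' @examples
#' beta_profile(0.98)
#' beta_profile("cos_fast")
#' beta_profile(function(t) 0.9 + 0.05 * sin(t), deriv = function(t) 0.05 * cos(t))
#' @export
beta_profile <- function(x, deriv = NULL) {
  if (inherits(x, "beta_profile")) return(x)
  if (is.numeric(x) && length(x) == 1L) {
    if (!is.finite(x) || x <= 0 || x > 1) {
      stop("constant fractal exponent must lie in (0, 1]", call. = FALSE)
    }
    val <- x
    return(structure(list(label = sprintf("const:%g", val),
                          fun = function(t) rep(val, length(t)),
                          dfun = function(t) rep(0, length(t)),
                          constant = val),
                     class = "beta_profile"))
  }
  if (is.function(x)) {
    return(structure(list(label = "custom", fun = x, dfun = deriv,
                          constant = NA_real_),
                     class = "beta_profile"))
  }
  if (is.character(x) && length(x) == 1L) {
    if (startsWith(x, "const:")) {
      return(beta_profile(as.numeric(sub("^const:", "", x))))
    }
    known <- list(
      cos_slow = list(f = function(t) 0.97 + 0.03 * cos(t / 10),
                      d = function(t) -0.003 * sin(t / 10)),
      cos_fast = list(f = function(t) 0.95 + 0.02 * cos(t),
                      d = function(t) -0.02 * sin(t)),
      tanh1p   = list(f = function(t) tanh(1 + t),
                      d = function(t) 1 / cosh(1 + t)^2),
      sigmoid  = list(f = function(t) 1 / (1 + exp(-t)),
                      d = function(t) {
                        s <- 1 / (1 + exp(-t)); s * (1 - s)
                      })
    )
    if (!x %in% names(known)) {
      stop("unknown beta profile '", x, "'; available: ",
           paste(c(names(known), "const:<value>"), collapse = ", "),
           call. = FALSE)
    }
    pk <- known[[x]]
    return(structure(list(label = x, fun = pk$f, dfun = pk$d,
                          constant = NA_real_),
                     class = "beta_profile"))
  }
  stop("cannot interpret `x` as a fractal-exponent profile", call. = FALSE)
}

#' @export
print.beta_profile <- function(x, ...) {
  cat("Fractal-exponent profile:", x$label, "\n")
  invisible(x)
}

#' Evaluate a fractal-exponent profile
#'
#' @param profile a [beta_profile()] (or anything coercible to one).
#' @param t time(s), `>= 0`.
#' @return Profile values clipped to `[1e-3, 1]`.
#' @examples
#' beta_eval("cos_fast", 1)   # 0.96081 to 5 d.p.
#' @export
beta_eval <- function(profile, t) {
  profile <- beta_profile(profile)
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  pmin(pmax(profile$fun(t), BETA_MIN), 1)
}

#' Derivative of a fractal-exponent profile
#'
#' Analytic mode returns the closed-form derivative of the (unclipped)
#' profile; forward-difference mode returns `(beta(t + dt) - beta(t)) / dt`,
#' the slope used by the variable-order kernel coefficient.
#'
#' @inheritParams beta_eval
#' @param dt step for the forward difference (required in that mode).
#' @param mode `"analytic"` or `"forward_difference"`.
#' @return Derivative value(s).
#' @examples
#' beta_deriv("cos_fast", 1)                      # -0.01683 to 5 d.p.
#' beta_deriv("cos_fast", 1, dt = 0.1, mode = "forward_difference")
#' @export
beta_deriv <- function(profile, t, dt = NULL,
                       mode = c("analytic", "forward_difference")) {
  profile <- beta_profile(profile)
  mode <- match.arg(mode)
  if (mode == "analytic") {
    if (is.null(profile$dfun)) {
      stop("profile '", profile$label, "' has no analytic derivative; ",
           "use mode = \"forward_difference\"", call. = FALSE)
    }
    return(profile$dfun(t))
  }
  if (is.null(dt) || dt <= 0) {
    stop("forward-difference mode needs `dt` > 0", call. = FALSE)
  }
  (beta_eval(profile, t + dt) - beta_eval(profile, t)) / dt
}

#' Growth rate of t^beta(t)
#'
#' The exact identity `d/dt t^beta(t) = t^beta(t) (beta'(t) log t + beta(t)/t)`,
#' the continuous ancestor of the variable-order kernel coefficient.  Singular
#' at `t = 0`.
#'
#' @inheritParams beta_deriv
#' @param t time, strictly positive.
#' @return The derivative of `t^beta(t)` at `t`.
#' @examples
#' tbeta_rate(beta_profile(0.5), 4)   # 0.5 * 4^(-0.5) = 0.25
#' @export
tbeta_rate <- function(profile, t,
                       mode = c("analytic", "forward_difference"),
                       dt = NULL) {
  profile <- beta_profile(profile)
  mode <- match.arg(mode)
  if (any(t <= 0)) stop("`t` must be strictly positive", call. = FALSE)
  b <- beta_eval(profile, t)
  bp <- beta_deriv(profile, t, dt = dt, mode = mode)
  t^b * (bp * log(t) + b / t)
}

#' Variable-order kernel coefficient kappa_n
#'
#' The discrete kernel coefficient
#' `kappa_n = t_n^beta(t_n) * ((beta(t_n + dt) - beta(t_n)) / dt * log(t_n) + beta(t_n) / t_n)`
#' with the forward-difference slope exactly as used by the variable-order
#' update.  For a constant exponent it reduces to the fixed-order scale factor
#' `beta * t_n^(beta - 1)`.
#'
#' @inheritParams beta_eval
#' @param t_n node time, strictly positive (the integrator bootstraps node 0
#'   separately).
#' @param dt time step.
#' @return The kernel coefficient, a finite scalar (or vector over `t_n`).
#' @examples
#' vo_kappa("cos_fast", 1, 0.1)   # 0.96081 to 5 d.p.
#' @export
vo_kappa <- function(profile, t_n, dt) {
  profile <- beta_profile(profile)
  if (any(t_n <= 0)) {
    stop("`t_n` must be strictly positive (node 0 is bootstrapped separately)",
         call. = FALSE)
  }
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  b <- beta_eval(profile, t_n)
  slope <- (beta_eval(profile, t_n + dt) - b) / dt
  t_n^b * (slope * log(t_n) + b / t_n)
}

#' Auxiliary variable-order term g_n
#'
#' `g_n = h * (beta'(t_n) log t_n + beta(t_n) / t_n) * t_n^beta(t_n)`, the
#' kernel-weighted right-hand-side sample of the variable-order scheme.  With
#' the forward-difference slope (the default) `g_n` equals `h * vo_kappa(...)`
#' identically.
#'
#' @inheritParams vo_kappa
#' @param h_val right-hand-side sample value.
#' @param mode slope mode for `beta'`: `"forward_difference"` (default,
#'   matching [vo_kappa()]) or `"analytic"`.
#' @return The weighted sample.
#' @examples
#' vo_gterm("cos_fast", 1, 0.1, h_val = 2.5)   # 2.40203 (5 d.p.)
#' @export
vo_gterm <- function(profile, t_n, dt, h_val,
                     mode = c("forward_difference", "analytic")) {
  profile <- beta_profile(profile)
  mode <- match.arg(mode)
  if (any(t_n <= 0)) stop("`t_n` must be strictly positive", call. = FALSE)
  b <- beta_eval(profile, t_n)
  bp <- if (mode == "forward_difference") {
    (beta_eval(profile, t_n + dt) - b) / dt
  } else {
    beta_deriv(profile, t_n, mode = "analytic")
  }
  h_val * (bp * log(t_n) + b / t_n) * t_n^b
}

#' Caputo-Fabrizio fractal-fractional integral of a sampled function
#'
#' Reference quadrature of
#' `alpha * beta / B(alpha) * int_0^t mu^(alpha-1) f(mu) dmu
#'  + beta * (1 - alpha) * t^(beta-1) / B(alpha) * f(t)`.
#' Product-trapezoidal rule: on each panel the sampled `f` is interpolated
#' linearly and integrated against the weight `mu^(alpha - 1)` with exact
#' power-law moments, so the integrable singularity at the origin costs no
#' accuracy.  A validation utility, not part of the solver hot path.
#'
#' @param f_vals function samples on the uniform grid from 0 to `t`
#'   (length `>= 2`).
#' @param alpha fractional order in `(0, 1)`.
#' @param beta fractal exponent in `(0, 1]`.
#' @param t upper limit, positive.
#' @return The integral value.
#' @examples
#' tt <- seq(0, 1, length.out = 2001)
#' cf_ff_integral(rep(1, length(tt)), alpha = 0.5, beta = 0.5, t = 1)
#' @export
cf_ff_integral <- function(f_vals, alpha, beta, t) {
  if (length(f_vals) < 2L) stop("need at least two samples", call. = FALSE)
  if (!is.finite(t) || t <= 0) stop("`t` must be positive", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  n <- length(f_vals)
  h <- t / (n - 1L)
  mu <- seq(0, t, length.out = n)
  # exact moments of the weight over each panel
  m_a <- diff(mu^alpha) / alpha                    # int mu^(a-1) dmu
  m_a1 <- diff(mu^(alpha + 1)) / (alpha + 1)       # int mu^a dmu
  f_lo <- f_vals[-n]
  slope <- diff(f_vals) / h
  weighted <- sum(f_lo * m_a + slope * (m_a1 - mu[-n] * m_a))
  bh <- cf_normalization(alpha)
  alpha * beta / bh * weighted +
    beta * (1 - alpha) * t^(beta - 1) / bh * f_vals[n]
}
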