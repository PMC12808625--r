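# Three-state glucose-insulin vector field, its Jacobian, and equilibria.
#
# The governing system (states y1, y2, y3; y3 is the beta-cell axis) is the
# cubic Lotka-Volterra-type regulatory model
#   y1' = -a1 y1 + a2 y1 y2 + a3 y2^2 + a4 y2^3 + a5 y3 + a6 y3^2 + a7 y3^3 + a20
#   y2' = -a8 y1 y2 - a9 y1^2 - a10 y1^3 + a11 y2 (1 - y2)
#          - a12 y3 - a13 y3^2 - a14 y3^3 + a21
#   y3' = a15 y2 + a16 y2^2 + a17 y2^3 - a18 y3 - a19 y2 y3
# with linear feedback -d1 (y1 + y2) on the first equation and -d3 (y1 + y3)
# on the third.  The sign of the a8 cross term appears with both signs in the
# source literature; the governing-system form (-a8 y1 y2) is canonical here
# and the alternative is available via `a8_sign = "positive"`.

# hot-path RHS: no validation, scalar in/out; s8 is -1 (canonical) or +1
.rhs3 <- function(y1, y2, y3, a, d1, d3, s8) {
  unname(c(-a[1L] * y1 + a[2L] * y1 * y2 + a[3L] * y2 * y2 + a[4L] * y2^3 +
      a[5L] * y3 + a[6L] * y3 * y3 + a[7L] * y3^3 + a[20L] - d1 * (y1 + y2),
    s8 * a[8L] * y1 * y2 - a[9L] * y1 * y1 - a[10L] * y1^3 +
      a[11L] * y2 * (1 - y2) - a[12L] * y3 - a[13L] * y3 * y3 -
      a[14L] * y3^3 + a[21L],
    a[15L] * y2 + a[16L] * y2 * y2 + a[17L] * y2^3 - a[18L] * y3 -
      a[19L] * y2 * y3 - d3 * (y1 + y3)))
}

.jac3 <- function(y1, y2, y3, a, d1, d3, s8) {
  matrix(c(
    -a[1L] + a[2L] * y2 - d1,
    a[2L] * y1 + 2 * a[3L] * y2 + 3 * a[4L] * y2 * y2 - d1,
    a[5L] + 2 * a[6L] * y3 + 3 * a[7L] * y3 * y3,
    s8 * a[8L] * y2 - 2 * a[9L] * y1 - 3 * a[10L] * y1 * y1,
    s8 * a[8L] * y1 + a[11L] * (1 - 2 * y2),
    -a[12L] - 2 * a[13L] * y3 - 3 * a[14L] * y3 * y3,
    -d3,
    a[15L] + 2 * a[16L] * y2 + 3 * a[17L] * y2 * y2 - a[19L] * y3,
    -a[18L] - a[19L] * y2 - d3
  ), nrow = 3L, byrow = TRUE)
}

check_state <- function(y) {
  if (!is.numeric(y) || length(y) != 3L) {
    stop("state must be a numeric vector of length 3", call. = FALSE)
  }
  if (any(!is.finite(y))) {
    stop("non-finite state component: y",
         which(!is.finite(y))[1L], call. = FALSE)
  }
  as.numeric(y)
}

a8_sign_value <- function(a8_sign) {
  a8_sign <- match.arg(a8_sign, c("negative", "positive"))
  if (a8_sign == "negative") -1 else 1
}

#' Right-hand side of the glucose-insulin system
#'
#' Evaluates the three coupled cubic rate equations, optionally with the
#' linear feedback terms `-d1 (y1 + y2)` (first equation) and `-d3 (y1 + y3)`
#' (third equation).  The system is autonomous; `t` is accepted for interface
#' symmetry with the integrators.
#'
#' @param t time (unused; the field is autonomous).
#' @param y numeric state vector `c(y1, y2, y3)`, finite.
#' @param params a [gi_parameters()] object (or named numeric of length 21).
#' @param gains `NULL` for the uncontrolled field, or a [gi_gains()] object /
#'   `c(d1, d3)` for the controlled one.
#' @param a8_sign sign convention for the `a8 y1 y2` term in the second
#'   equation: `"negative"` (governing-system form, default) or `"positive"`.
#' @return Numeric vector of the three rates.
#' @examples
#' gi_rhs(0, c(0, 0, 0), gi_parameters())          # (a20, a21, 0)
#' gi_rhs(0, c(1, 1, 1), gi_parameters(), gi_gains(0.2, 0.1))
#' @export
gi_rhs <- function(t = 0, y, params = gi_parameters(), gains = NULL,
                   a8_sign = c("negative", "positive")) {
  y <- check_state(y)
  a <- as_params(params)
  g <- as_gains(gains)
  .rhs3(y[1L], y[2L], y[3L], a, g$d1, g$d3, a8_sign_value(a8_sign))
}

#' Analytic Jacobian of the controlled glucose-insulin field
#'
#' Partial derivatives of [gi_rhs()] with respect to the state, including the
#' feedback contributions (`-d1` on entries (1,1) and (1,2), `-d3` on (3,1)
#' and (3,3)).
#'
#' @inheritParams gi_rhs
#' @return A 3 x 3 numeric matrix.
#' @examples
#' gi_jacobian(y = c(0.5, 1, 1), gains = gi_gains(0.2, 0.1))
#' @export
gi_jacobian <- function(t = 0, y, params = gi_parameters(), gains = NULL,
                        a8_sign = c("negative", "positive")) {
  y <- check_state(y)
  a <- as_params(params)
  g <- as_gains(gains)
  .jac3(y[1L], y[2L], y[3L], a, g$d1, g$d3, a8_sign_value(a8_sign))
}

#' Equilibrium of the controlled system by damped Newton iteration
#'
#' Finds a root of the (controlled) vector field starting from `y_init`, using
#' Newton steps with the analytic Jacobian and step halving whenever a full
#' step fails to reduce the residual.  Convergence is declared when the
#' sup-norm residual drops below `tol`.  Non-convergence is reported
#' explicitly (`converged = FALSE` with the best iterate), never silently.
#'
#' @inheritParams gi_rhs
#' @param y_init starting state.
#' @param tol sup-norm residual tolerance (default `1e-10`).
#' @param max_iter maximum Newton iterations (default 200).
#' @return A list of class `"gi_equilibrium"`: `y` (the root or best iterate),
#'   `residual` (sup-norm of the field there), `converged`, `iterations`.
#' @examples
#' eq <- gi_equilibrium(y_init = c(0.5, 1, 1), gains = NULL)
#' eq$residual
#' @export
gi_equilibrium <- function(params = gi_parameters(), gains = NULL,
                           y_init = c(0.5, 1, 1), tol = 1e-10,
                           max_iter = 200L,
                           a8_sign = c("negative", "positive")) {
  y <- check_state(y_init)
  a <- as_params(params)
  g <- as_gains(gains)
  s8 <- a8_sign_value(a8_sign)
  f <- .rhs3(y[1L], y[2L], y[3L], a, g$d1, g$d3, s8)
  res <- max(abs(f))
  it <- 0L
  while (res > tol && it < max_iter) {
    J <- .jac3(y[1L], y[2L], y[3L], a, g$d1, g$d3, s8)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) {
      # rank-deficient Jacobian: minimum-norm (pseudo-inverse) Newton step
      sv <- svd(J)
      keep <- sv$d > max(sv$d) * 1e-12
      if (!any(keep)) break
      step <- -sv$v[, keep, drop = FALSE] %*%
        ((t(sv$u[, keep, drop = FALSE]) %*% f) / sv$d[keep])
      step <- as.numeric(step)
    }
    lam <- 1
    repeat {
      y_new <- y + lam * step
      f_new <- .rhs3(y_new[1L], y_new[2L], y_new[3L], a, g$d1, g$d3, s8)
      if (all(is.finite(f_new)) && max(abs(f_new)) < res) break
      lam <- lam / 2
      if (lam < 2^-20) { y_new <- y; f_new <- f; break }
    }
    if (identical(y_new, y)) break  # damping exhausted, no progress
    y <- y_new; f <- f_new; res <- max(abs(f)); it <- it + 1L
  }
  structure(list(y = y, residual = res, converged = res <= tol,
                 iterations = it),
            class = "gi_equilibrium")
}

#' @export
print.gi_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium search: %s after %d iteration(s)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  y* = (", paste(format(x$y, digits = 10), collapse = ", "), ")\n")
  cat("  sup-norm residual:", format(x$residual, digits = 4), "\n")
  invisible(x)
}
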