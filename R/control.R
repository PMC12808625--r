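# Linearization-based feedback design: closed-loop assembly A - B K with
# K = [d1 0 d3], eigenvalue reports, the proportional gain-tuning rule
# d_i = k_i |Re(lambda_max)|, and gain sweeps.

#' Nominal linearized subsystem used for gain tuning
#'
#' The 3 x 3 state matrix and input map of the linearized benchmark on which
#' the feedback gains are shifted:
#' `A = [[0, 1, 0], [-2, -0.1, 1], [0, -3, -0.2]]`, `B = (0, 1, 0)'`.
#'
#' @return A list with elements `A` (3 x 3) and `B` (3 x 1).
#' @examples
#' sys <- nominal_linearization()
#' closed_loop(sys$A, sys$B, gain_row(3, 2))
#' @export
nominal_linearization <- function() {
  list(A = matrix(c(0, 1, 0, -2, -0.1, 1, 0, -3, -0.2), 3, 3, byrow = TRUE),
       B = matrix(c(0, 1, 0), 3, 1))
}

#' Feedback gain row K = \[d1, 0, d3\]
#'
#' @param d1,d3 feedback gains.
#' @return A 1 x 3 matrix with zero middle entry.
#' @export
gain_row <- function(d1, d3) {
  matrix(c(d1, 0, d3), 1, 3)
}

#' Closed-loop system matrix
#'
#' `A_cl = A - B K`.
#'
#' @param A square state matrix.
#' @param B input map, conformable with `K`.
#' @param K gain row, see [gain_row()].
#' @return The closed-loop matrix.
#' @examples
#' sys <- nominal_linearization()
#' closed_loop(sys$A, sys$B, gain_row(3, 2))[2, ]   # (-5, -0.1, -1)
#' @export
closed_loop <- function(A, B, K) {
  if (!is.matrix(A) || nrow(A) != ncol(A)) {
    stop("`A` must be a square matrix", call. = FALSE)
  }
  if (!is.matrix(B)) B <- matrix(B, ncol = 1)
  if (!is.matrix(K)) K <- matrix(K, nrow = 1)
  if (nrow(B) != nrow(A) || ncol(K) != ncol(A) || ncol(B) != nrow(K)) {
    stop("shapes of A, B, K are not conformable", call. = FALSE)
  }
  A - B %*% K
}

#' Eigenvalue report of a system matrix
#'
#' Dense eigendecomposition with the derived spectral abscissa (largest real
#' part) and linear-stability flag.
#'
#' @param M square numeric matrix with finite entries.
#' @return A list of class `"spectral_report"`: `eigenvalues` (complex,
#'   ordered by decreasing real part), `spectral_abscissa`, `stable`
#'   (abscissa `< 0`), `trace`.
#' @examples
#' spectral_report(diag(c(-1, -2, -3)))$stable
#' @export
spectral_report <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop("`M` must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(M))) stop("`M` has non-finite entries", call. = FALSE)
  ev <- eigen(M, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  structure(list(eigenvalues = ev,
                 spectral_abscissa = max(Re(ev)),
                 stable = max(Re(ev)) < 0,
                 trace = sum(diag(M))),
            class = "spectral_report")
}

#' @export
print.spectral_report <- function(x, ...) {
  cat("Eigenvalues:", paste(format(x$eigenvalues, digits = 5),
                            collapse = ", "), "\n")
  cat(sprintf("Spectral abscissa: %.5f (%s)\n", x$spectral_abscissa,
              if (x$stable) "stable" else "not stable"))
  invisible(x)
}

#' Proportional gain tuning from the dominant eigenvalue
#'
#' The eigenvalue-shift rule `d_i = k_i * |Re(lambda_max)|` for `i = 1, 3`.
#' Multipliers outside the nominal range \[0.1, 0.3\] trigger a warning (the
#' rule is advisory, not a hard constraint).
#'
#' @param lambda_max_re real part of the dominant eigenvalue of the
#'   uncontrolled linearization.
#' @param k1,k3 tuning multipliers.
#' @return A [gi_gains()] object with the derived `d1`, `d3`.
#' @examples
#' tune_gains(0.08, 0.25, 0.25)   # d1 = d3 = 0.02
#' @export
tune_gains <- function(lambda_max_re, k1 = 0.25, k3 = 0.25) {
  if (!is.numeric(lambda_max_re) || !is.finite(lambda_max_re)) {
    stop("`lambda_max_re` must be finite", call. = FALSE)
  }
  if (k1 < 0.1 || k1 > 0.3 || k3 < 0.1 || k3 > 0.3) {
    warning("tuning multiplier outside the nominal range [0.1, 0.3]",
            call. = FALSE)
  }
  gi_gains(d1 = k1 * abs(lambda_max_re), d3 = k3 * abs(lambda_max_re))
}

#' Spectral abscissa over a grid of gain pairs
#'
#' Evaluates the closed-loop spectral abscissa of `A - B [d1 0 d3]` over the
#' Cartesian grid `d1_grid` x `d3_grid` and flags the stability boundary
#' (sign changes of the abscissa along the grid).
#'
#' @param A,B system matrices, see [closed_loop()].
#' @param d1_grid,d3_grid numeric grids of gains.
#' @return A data frame of class `"gain_sweep"` with columns `d1`, `d3`,
#'   `abscissa`, `stable`.
#' @examples
#' sys <- nominal_linearization()
#' gain_sweep(sys$A, sys$B, c(0, 1, 3, 5), c(0, 1, 2, 3))
#' @export
gain_sweep <- function(A, B, d1_grid, d3_grid) {
  if (any(!is.finite(d1_grid)) || any(!is.finite(d3_grid))) {
    stop("gain grids must be finite", call. = FALSE)
  }
  grid <- expand.grid(d1 = d1_grid, d3 = d3_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$abscissa <- vapply(seq_len(nrow(grid)), function(i) {
    spectral_report(closed_loop(A, B, gain_row(grid$d1[i], grid$d3[i])))$
      spectral_abscissa
  }, numeric(1))
  grid$stable <- grid$abscissa < 0
  class(grid) <- c("gain_sweep", "data.frame")
  grid
}
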