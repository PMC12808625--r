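#' Kinetic parameters of the glucose-insulin regulatory model
#'
#' Builds the set of 21 kinetic constants `a1..a21` of the three-state
#' glucose-insulin system.  Called with no arguments it returns the reference
#' parameterization (baseline glucose decay `a1 = 2.04` per minute, insulin
#' action on glucose `a2 = 0.10`, basal influx terms `a20 = -0.19`,
#' `a21 = -0.56`, and so on); individual constants can be overridden by name.
#'
#' @param ... named overrides, e.g. `gi_parameters(a1 = 1.5)`.  Names must be
#'   among `a1..a21` and values finite scalars.
#' @return A named numeric vector of length 21 with class `"gi_parameters"`.
#' @examples
#' p <- gi_parameters()
#' p["a1"]
#' gi_parameters(a11 = 0.25)["a11"]
#' @export
gi_parameters <- function(...) {
  p <- c(
    a1 = 2.04, a2 = 0.10, a3 = 1.09, a4 = -1.08, a5 = 0.03,
    a6 = -0.06, a7 = 2.01, a8 = 0.22, a9 = -3.84, a10 = -1.20,
    a11 = 0.30, a12 = 1.37, a13 = -0.30, a14 = 0.22, a15 = 0.30,
    a16 = -1.35, a17 = 0.50, a18 = -0.42, a19 = -0.15, a20 = -0.19,
    a21 = -0.56
  )
  ov <- list(...)
  if (length(ov)) {
    if (is.null(names(ov)) || any(!nzchar(names(ov)))) {
      stop("parameter overrides must be named (a1..a21)", call. = FALSE)
    }
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) {
      stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    for (nm in names(ov)) {
      v <- ov[[nm]]
      if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
        stop("parameter ", nm, " must be a finite numeric scalar", call. = FALSE)
      }
      p[nm] <- as.numeric(v)
    }
  }
  structure(p, class = "gi_parameters")
}

#' @export
print.gi_parameters <- function(x, ...) {
  cat("Glucose-insulin model parameters (a1..a21):\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Linear feedback gains
#'
#' Container for the two feedback gains of the controlled system: `d1` acts on
#' the first state equation through `-d1 * (y1 + y2)` and `d3` on the third
#' through `-d3 * (y1 + y3)`.  Optional tuning multipliers `k1`, `k3` (the
#' proportional factors of the eigenvalue-shift rule, nominally in
#' \[0.1, 0.3\]) are carried as metadata.
#'
#' @param d1,d3 non-negative feedback gains.
#' @param k1,k3 optional tuning multipliers used to derive the gains; a warning
#'   is issued when they fall outside \[0.1, 0.3\].
#' @return A list with class `"gi_gains"` and elements `d1`, `d3`, `k1`, `k3`.
#' @examples
#' gi_gains(0.2, 0.1)
#' @export
gi_gains <- function(d1 = 0.2, d3 = 0.1, k1 = NULL, k3 = NULL) {
  for (v in list(d1 = d1, d3 = d3)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("gains must be finite numeric scalars", call. = FALSE)
    }
  }
  if (d1 < 0 || d3 < 0) {
    stop("feedback gains must be non-negative (got d1 = ", d1,
         ", d3 = ", d3, ")", call. = FALSE)
  }
  for (k in list(k1, k3)) {
    if (!is.null(k) && (k < 0.1 || k > 0.3)) {
      warning("tuning multiplier outside the nominal range [0.1, 0.3]",
              call. = FALSE)
    }
  }
  structure(list(d1 = d1, d3 = d3, k1 = k1, k3 = k3), class = "gi_gains")
}

#' @export
print.gi_gains <- function(x, ...) {
  cat(sprintf("Feedback gains: d1 = %g, d3 = %g\n", x$d1, x$d3))
  if (!is.null(x$k1) || !is.null(x$k3)) {
    cat(sprintf("  (tuning multipliers k1 = %s, k3 = %s)\n",
                format(x$k1), format(x$k3)))
  }
  invisible(x)
}

#' State bounds for the Lipschitz analysis
#'
#' Sup-norm bounds `K_y1`, `K_y2`, `K_y3` on the three states, used by
#' [lipschitz_constants()].
#'
#' @param K_y1,K_y2,K_y3 non-negative bounds.
#' @return Named numeric vector of length 3 with class `"gi_state_bounds"`.
#' @export
gi_state_bounds <- function(K_y1 = 0, K_y2 = 0, K_y3 = 0) {
  b <- c(K_y1 = K_y1, K_y2 = K_y2, K_y3 = K_y3)
  if (!all(is.finite(b)) || any(b < 0)) {
    stop("state bounds must be finite and non-negative", call. = FALSE)
  }
  structure(b, class = "gi_state_bounds")
}

# coerce user input (vector or gi_parameters) to plain named numeric of length 21
as_params <- function(p) {
  if (inherits(p, "gi_parameters")) return(unclass(p))
  if (is.numeric(p) && length(p) == 21L) {
    names(p) <- paste0("a", 1:21)
    return(p)
  }
  stop("`params` must be a gi_parameters object or a numeric vector of length 21",
       call. = FALSE)
}

as_gains <- function(g) {
  if (is.null(g)) return(list(d1 = 0, d3 = 0))
  if (inherits(g, "gi_gains")) return(g)
  if (is.numeric(g) && length(g) == 2L) return(gi_gains(g[1], g[2]))
  stop("`gains` must be NULL, a gi_gains object, or a numeric vector c(d1, d3)",
       call. = FALSE)
}
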