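# Trajectory container shared by both integrators.

new_trajectory <- function(time, y, scheme, alpha, beta_label, gains, dt,
                           horizon, termination, a8_sign) {
  colnames(y) <- c("y1", "y2", "y3")
  structure(list(time = time, y = y, scheme = scheme, alpha = alpha,
                 beta = beta_label, gains = gains, dt = dt,
                 horizon = horizon, termination = termination,
                 a8_sign = a8_sign),
            class = "gi_trajectory")
}

#' @export
print.gi_trajectory <- function(x, ...) {
  cat(sprintf("CF-FF trajectory (%s scheme), alpha = %g, beta = %s\n",
              x$scheme, x$alpha, x$beta))
  cat(sprintf("  gains d1 = %g, d3 = %g; dt = %g; %d nodes on [0, %g]\n",
              x$gains$d1, x$gains$d3, x$dt, length(x$time),
              x$time[length(x$time)]))
  cat("  termination:", x$termination, "\n")
  invisible(x)
}

#' @export
summary.gi_trajectory <- function(object, late_from = 20, ...) {
  n <- length(object$time)
  out <- list(
    termination = object$termination,
    final_time = object$time[n],
    final_state = object$y[n, ],
    sup_norm = max(abs(object$y)),
    late_sup_norm = sup_norm(object, from = late_from)
  )
  class(out) <- "summary.gi_trajectory"
  out
}

#' @export
print.summary.gi_trajectory <- function(x, ...) {
  cat("Trajectory summary\n")
  cat("  termination:      ", x$termination, "\n")
  cat("  final time:       ", format(x$final_time), "\n")
  cat("  final state:      (",
      paste(format(x$final_state, digits = 6), collapse = ", "), ")\n")
  cat("  sup-norm:         ", format(x$sup_norm, digits = 6), "\n")
  cat("  late sup-norm:    ", format(x$late_sup_norm, digits = 6), "\n")
  invisible(x)
}

#' @export
as.data.frame.gi_trajectory <- function(x, ...) {
  data.frame(t = x$time, y1 = x$y[, 1L], y2 = x$y[, 2L], y3 = x$y[, 3L])
}

#' Late-window sup-norm of a trajectory
#'
#' Maximum absolute state value over a time window, the scalar used to compare
#' controlled against uncontrolled runs.  Returns `Inf` for trajectories
#' flagged as diverged (a blown-up run dominates any bounded one) and `NA`
#' when the window is empty.
#'
#' @param traj a `gi_trajectory`.
#' @param from,to window limits (defaults: 20 to the end of the run).
#' @return A scalar.
#' @export
sup_norm <- function(traj, from = 20, to = Inf) {
  stopifnot(inherits(traj, "gi_trajectory"))
  if (traj$termination == "diverged") return(Inf)
  sel <- traj$time >= from & traj$time <= to
  if (!any(sel)) return(NA_real_)
  max(abs(traj$y[sel, , drop = FALSE]))
}

#' @export
plot.gi_trajectory <- function(x, which = c("series", "phase"), ...) {
  which <- match.arg(which)
  if (which == "series") {
    op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1, 1))
    on.exit(graphics::par(op))
    labs <- c("y1 (glucose axis)", "y2 (insulin axis)", "y3 (beta-cell axis)")
    for (i in 1:3) {
      graphics::plot(x$time, x$y[, i], type = "l", xlab = "t",
                     ylab = labs[i], ...)
    }
  } else {
    graphics::plot(x$y[, 1L], x$y[, 2L], type = "l",
                   xlab = "y1", ylab = "y2", ...)
  }
  invisible(x)
}
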