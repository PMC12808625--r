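# Preset simulation scenarios: one row per published phase-portrait /
# time-series panel (figure ids 2-13, matching gain-table rows 1-12), each
# carrying the fractional orders, exponent profile and feedback gains of that
# run.  Defaults dt = 0.001, T = 120.

# three reference initial conditions
GI_INITIAL_STATES <- list(c(0, 1.5, 1), c(0.5, 1, 1), c(1.4, -1.5, 1.31))

.scenario_rows <- function() {
  # figure id = gain-table row + 1
  data.frame(
    figure = 2:13,
    table_row = 1:12,
    alpha = c(1, 1, 0.98, 0.98, 1, 1, 1, 1, 0.98, 0.98, 1, 1),
    beta = c("const:1", "const:0.98", "const:1", "cos_slow", "tanh1p",
             "sigmoid", "const:1", "const:0.98", "const:1", "cos_slow",
             "tanh1p", "sigmoid"),
    d1 = c(0.20, 0.20, 0.20, 0.22, 0.25, 0.25,
           0.20, 0.20, 0.20, 0.22, 0.25, 0.25),
    d3 = c(0.10, 0.10, 0.10, 0.12, 0.12, 0.15,
           0.10, 0.10, 0.10, 0.12, 0.12, 0.15),
    memory = c("constant", "constant", "constant",
               "oscillatory variable order", "gradual memory accumulation",
               "sigmoidal adaptation", "constant", "constant", "constant",
               "time-varying adaptive", "delayed stabilization",
               "sigmoidal delay"),
    stringsAsFactors = FALSE
  )
}

#' Table of preset simulation scenarios
#'
#' One row per preset: figure id, gain-table row, fractional order `alpha`,
#' exponent profile, feedback gains and memory-type label.
#'
#' @return A data frame of the 12 presets.
#' @examples
#' scenario_table()
#' @export
scenario_table <- function() .scenario_rows()

#' Retrieve one scenario preset
#'
#' @param figure_id figure id in `2:13`.
#' @return A list of class `"gi_scenario"`: `figure`, `alpha`, `beta`
#'   (profile label), `gains`, `dt`, `T`, `y0_options`, `memory`.
#' @examples
#' get_scenario(5)   # alpha = 0.98, cos_slow, gains (0.22, 0.12)
#' @export
get_scenario <- function(figure_id) {
  tab <- .scenario_rows()
  if (length(figure_id) != 1L || !figure_id %in% tab$figure) {
    stop("unknown figure id ", figure_id, "; valid ids: ",
         paste(tab$figure, collapse = ", "), call. = FALSE)
  }
  row <- tab[tab$figure == figure_id, ]
  structure(list(figure = row$figure, alpha = row$alpha, beta = row$beta,
                 gains = gi_gains(row$d1, row$d3), dt = 0.001, T = 120,
                 y0_options = GI_INITIAL_STATES, memory = row$memory),
            class = "gi_scenario")
}

#' @export
print.gi_scenario <- function(x, ...) {
  cat(sprintf("Scenario (figure %d): alpha = %g, beta = %s, gains (%g, %g)\n",
              x$figure, x$alpha, x$beta, x$gains$d1, x$gains$d3))
  cat("  memory type:", x$memory, "\n")
  invisible(x)
}

#' Run a preset scenario
#'
#' Simulates a preset with and/or without feedback control and summarizes the
#' contrast: late-window sup-norms and divergence flags.  The solver (fixed
#' versus variable order) follows the exponent profile automatically.
#'
#' @param figure_id preset id, see [get_scenario()].
#' @param controlled `"both"` (default), `"controlled"` or `"uncontrolled"`.
#' @param y0_index which reference initial state to use: 1 = `(0, 1.5, 1)`
#'   (default), 2 = `(0.5, 1, 1)`, 3 = `(1.4, -1.5, 1.31)`.
#' @param dt,T optional overrides of the preset grid.
#' @param late_from start of the comparison window (default 20).
#' @return A list of class `"gi_scenario_run"` with `scenario`, the
#'   trajectories (`controlled` / `uncontrolled`, as requested) and a
#'   `summary` data frame.
#' @examples
#' run <- run_scenario(2, T = 5, dt = 0.01, late_from = 1)
#' run$summary
#' @export
run_scenario <- function(figure_id,
                         controlled = c("both", "controlled", "uncontrolled"),
                         y0_index = 1L, dt = NULL, T = NULL, late_from = 20) {
  controlled <- match.arg(controlled)
  sc <- get_scenario(figure_id)
  if (length(y0_index) != 1L || !y0_index %in% 1:3) {
    stop("`y0_index` must be 1, 2 or 3", call. = FALSE)
  }
  y0 <- sc$y0_options[[y0_index]]
  dt <- if (is.null(dt)) sc$dt else dt
  T <- if (is.null(T)) sc$T else T
  runs <- list()
  if (controlled %in% c("both", "controlled")) {
    runs$controlled <- gi_simulate(y0, gains = sc$gains, alpha = sc$alpha,
                                   beta = sc$beta, dt = dt, T = T)
  }
  if (controlled %in% c("both", "uncontrolled")) {
    runs$uncontrolled <- gi_simulate(y0, gains = NULL, alpha = sc$alpha,
                                     beta = sc$beta, dt = dt, T = T)
  }
  summ <- do.call(rbind, lapply(names(runs), function(nm) {
    tr <- runs[[nm]]
    data.frame(run = nm, termination = tr$termination,
               diverged = tr$termination == "diverged",
               late_sup_norm = sup_norm(tr, from = late_from),
               stringsAsFactors = FALSE)
  }))
  structure(c(list(scenario = sc, summary = summ), runs),
            class = "gi_scenario_run")
}

#' @export
print.gi_scenario_run <- function(x, ...) {
  print(x$scenario)
  print(x$summary, row.names = FALSE)
  invisible(x)
}
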