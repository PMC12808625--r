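# Run configuration (YAML/JSON) and trajectory CSV + JSON-sidecar I/O.

.config_defaults <- function() {
  list(
    params = as.list(unclass(gi_parameters())),
    alpha = 1,
    beta = "const:1",
    gains = list(d1 = 0.2, d3 = 0.1),
    y0 = c(0, 1.5, 1),
    solver = list(dt = 0.001, T = 120, rel_tol = 1e-6, abs_tol = 1e-8,
                  stop_delta = 1e-8, scheme = "auto", newton_order = 3),
    a8_sign = "negative",
    seed = NA_integer_,
    log_level = "info"
  )
}

# FNV-1a 32-bit content hash, exact in double arithmetic via 16-bit splits
config_hash <- function(cfg) {
  s <- as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                                     null = "null"))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b))
    hi <- h %/% 65536
    h <- ((hi * p) %% 65536) * 65536 + lo * p
    h <- h %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

validate_config <- function(cfg) {
  defs <- .config_defaults()
  unknown <- setdiff(names(cfg), names(defs))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defs, cfg)
  if (!is.numeric(out$alpha) || out$alpha <= 0 || out$alpha > 1) {
    stop("config field `alpha`: must lie in (0, 1]", call. = FALSE)
  }
  bp <- tryCatch(beta_profile(out$beta), error = function(e) {
    stop("config field `beta`: ", conditionMessage(e), call. = FALSE)
  })
  if (!is.list(out$gains) || is.null(out$gains$d1) || is.null(out$gains$d3)) {
    stop("config field `gains`: needs d1 and d3", call. = FALSE)
  }
  if (out$gains$d1 < 0 || out$gains$d3 < 0) {
    stop("config field `gains`: gains must be non-negative", call. = FALSE)
  }
  y0 <- as.numeric(out$y0)
  if (length(y0) != 3L || any(!is.finite(y0))) {
    stop("config field `y0`: must be three finite values", call. = FALSE)
  }
  out$y0 <- y0
  sv <- out$solver
  if (!is.numeric(sv$dt) || sv$dt <= 0 || !is.numeric(sv$T) || sv$T <= 0) {
    stop("config field `solver`: dt and T must be positive", call. = FALSE)
  }
  if (!sv$scheme %in% c("auto", "fixed", "variable")) {
    stop("config field `solver$scheme`: must be auto, fixed or variable",
         call. = FALSE)
  }
  pr <- out$params
  if (length(pr) != 21L || !all(paste0("a", 1:21) %in% names(pr))) {
    stop("config field `params`: needs all of a1..a21", call. = FALSE)
  }
  out$params <- do.call(gi_parameters, pr[paste0("a", 1:21)])
  if (!out$a8_sign %in% c("negative", "positive")) {
    stop("config field `a8_sign`: must be 'negative' or 'positive'",
         call. = FALSE)
  }
  class(out) <- "gi_run_config"
  out
}

#' Default run configuration
#'
#' The fully populated configuration used when a file provides no overrides:
#' reference parameters, `alpha = 1`, constant exponent 1, gains
#' `(0.2, 0.1)`, `y0 = (0, 1.5, 1)`, `dt = 0.001`, `T = 120`.
#'
#' @return A validated `gi_run_config` list.
#' @export
default_run_config <- function() validate_config(list())

#' Load and validate a run configuration
#'
#' Reads a YAML or JSON configuration, fills in defaults, validates every
#' field and rejects unknown keys.  An empty file yields
#' [default_run_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `gi_run_config` list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
}

#' Run a simulation described by a configuration
#'
#' @param config a `gi_run_config` (from [load_run_config()] or
#'   [default_run_config()]).
#' @return A `gi_trajectory`.
#' @export
simulate_config <- function(config) {
  stopifnot(inherits(config, "gi_run_config"))
  if (!is.null(config$seed) && !is.na(config$seed)) set.seed(config$seed)
  gi_simulate(config$y0, params = config$params,
              gains = gi_gains(config$gains$d1, config$gains$d3),
              alpha = config$alpha, beta = config$beta,
              dt = config$solver$dt, T = config$solver$T,
              scheme = config$solver$scheme,
              newton_order = config$solver$newton_order,
              stop_delta = config$solver$stop_delta,
              a8_sign = config$a8_sign)
}

trajectory_metadata <- function(traj) {
  meta <- list(scheme = traj$scheme, alpha = traj$alpha, beta = traj$beta,
               gains = traj$gains, dt = traj$dt, horizon = traj$horizon,
               termination = traj$termination, a8_sign = traj$a8_sign)
  meta$config_hash <- config_hash(meta)
  meta
}

#' Write a trajectory as CSV with a JSON metadata sidecar
#'
#' The CSV has header `t,y1,y2,y3` with full double precision (round-trip
#' exact); metadata (scheme, orders, gains, grid, termination reason and a
#' configuration hash) goes to `<path>.json`.
#'
#' @param traj a `gi_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gi_trajectory"))
  df <- as.data.frame(traj)
  lines <- c("t,y1,y2,y3",
             sprintf("%.17g,%.17g,%.17g,%.17g", df$t, df$y1, df$y2, df$y3))
  writeLines(lines, path)
  meta <- trajectory_metadata(traj)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' Restores the `gi_trajectory` bit-exactly (states and grid) from the CSV
#' and its JSON sidecar.  Malformed files raise parse errors naming the
#' offending line or column.
#'
#' @param path CSV path.
#' @return A `gi_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !identical(lines[1L], "t,y1,y2,y3")) {
    stop("line 1: expected header 't,y1,y2,y3'", call. = FALSE)
  }
  body <- lines[-1L]
  parts <- strsplit(body, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 4L)) {
    stop("line ", which(nfield != 4L)[1L] + 1L,
         ": expected 4 comma-separated fields, found ",
         nfield[nfield != 4L][1L], call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = 4L, byrow = TRUE))
  if (anyNA(vals)) {
    stop("line ", which(rowSums(is.na(vals)) > 0)[1L] + 1L,
         ": non-numeric field", call. = FALSE)
  }
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::fromJSON(side) else NULL
  new_trajectory(
    time = vals[, 1L], y = vals[, 2:4, drop = FALSE],
    scheme = if (!is.null(meta)) meta$scheme else NA_character_,
    alpha = if (!is.null(meta)) meta$alpha else NA_real_,
    beta_label = if (!is.null(meta)) meta$beta else NA_character_,
    gains = if (!is.null(meta)) meta$gains else list(d1 = NA_real_, d3 = NA_real_),
    dt = if (!is.null(meta)) meta$dt else NA_real_,
    horizon = if (!is.null(meta)) meta$horizon else NA_real_,
    termination = if (!is.null(meta)) meta$termination else NA_character_,
    a8_sign = if (!is.null(meta)) meta$a8_sign else NA_character_
  )
}
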