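#' Construct a trajectory
#'
#' A trajectory is one participant-session's ordered sequence of
#' time-stamped 2D positions in arena coordinates, nominally sampled at a
#' fixed rate (20 Hz for the standard session).
#'
#' @param t Sample times in seconds, strictly increasing.
#' @param x,y Positions in meters, arena coordinates.
#' @param participant_id,experiment_id Identifier strings.
#' @param nominal_rate Nominal samples per second.
#' @param arena Optional [arena_spec()]; when supplied, positions are
#'   validated against the arena bounds.
#'
#' @return An object of class `oft_trajectory`: a list with numeric vectors
#'   `t`, `x`, `y` and metadata fields.
#' @examples
#' tr <- trajectory(t = 0:2 / 20, x = c(50, 51, 52), y = c(50, 50, 50))
#' n_samples(tr)
#' @export
trajectory <- function(t, x, y, participant_id = "unknown",
                       experiment_id = "unknown", nominal_rate = 20,
                       arena = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  if (length(t) != length(x) || length(t) != length(y)) {
    stop("'t', 'x' and 'y' must have equal length", call. = FALSE)
  }
  if (anyNA(t) || anyNA(x) || anyNA(y)) {
    stop("trajectory samples must not contain missing values", call. = FALSE)
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(arena)) {
    stopifnot(inherits(arena, "oft_arena"))
    check_in_arena(x, y, arena$side_length)
  }
  structure(
    list(t = t, x = x, y = y,
         participant_id = as.character(participant_id),
         experiment_id = as.character(experiment_id),
         nominal_rate = as.numeric(nominal_rate)),
    class = "oft_trajectory"
  )
}

#' @rdname trajectory
#' @param traj An `oft_trajectory`.
#' @export
n_samples <- function(traj) {
  stopifnot(inherits(traj, "oft_trajectory"))
  length(traj$t)
}

#' @export
print.oft_trajectory <- function(x, ...) {
  dur <- if (length(x$t) > 1) diff(range(x$t)) else 0
  cat(sprintf(
    "Trajectory '%s' (%s): %d samples over %.1f s at nominal %g Hz\n",
    x$participant_id, x$experiment_id, length(x$t), dur, x$nominal_rate))
  invisible(x)
}

#' Canonical position-log dialect
#'
#' The canonical log is UTF-8 CSV with header `t_s,x_m,y_m`, one sample per
#' row, 6-decimal fixed precision, preceded by `# key=value` metadata
#' comment lines. `log_dialect()` describes how to map other column layouts
#' onto this scheme when reading.
#'
#' @param time,x,y Column names holding time and coordinates.
#' @param time_scale,length_scale Multipliers converting the file's units to
#'   seconds and meters (e.g. `time_scale = 1e-3` for millisecond stamps).
#'
#' @return A list of class `oft_dialect`.
#' @export
log_dialect <- function(time = "t_s", x = "x_m", y = "y_m",
                        time_scale = 1, length_scale = 1) {
  structure(list(time = time, x = x, y = y,
                 time_scale = time_scale, length_scale = length_scale),
            class = "oft_dialect")
}

#' Read a position log
#'
#' Reads a CSV position log into a validated [trajectory()]. Metadata
#' stored in leading `# key=value` comment lines (participant_id,
#' experiment_id, nominal_rate, arena side) is recovered when present.
#' Rows with unparsable fields are dropped with a warning giving their
#' count (or rejected outright when `strict = TRUE`).
#'
#' @param path File to read.
#' @param dialect A [log_dialect()] mapping columns and units.
#' @param arena Optional [arena_spec()] for bounds validation.
#' @param strict Reject files containing malformed rows instead of dropping
#'   them.
#' @param clamp Clamp slightly out-of-bounds positions onto the arena
#'   boundary instead of failing validation (off by default).
#' @param sort_time Sort samples by time before validation (off by default;
#'   with it off, non-monotone time stamps are an error).
#'
#' @return An `oft_trajectory`.
#' @export
read_log <- function(path, dialect = log_dialect(), arena = NULL,
                     strict = FALSE, clamp = FALSE, sort_time = FALSE) {
  stopifnot(inherits(dialect, "oft_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)

  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- m[3]
  }

  df <- utils::read.csv(text = lines[!grepl("^#", lines)],
                        stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c(dialect$time, dialect$x, dialect$y)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path, call. = FALSE)
  }

  t <- suppressWarnings(as.numeric(df[[dialect$time]])) * dialect$time_scale
  x <- suppressWarnings(as.numeric(df[[dialect$x]])) * dialect$length_scale
  y <- suppressWarnings(as.numeric(df[[dialect$y]])) * dialect$length_scale
  bad <- is.na(t) | is.na(x) | is.na(y)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("format error: %d malformed row(s) in %s", sum(bad), path),
           call. = FALSE)
    }
    warning(sprintf("dropped %d malformed row(s) from %s", sum(bad), path),
            call. = FALSE)
    t <- t[!bad]; x <- x[!bad]; y <- y[!bad]
  }

  if (sort_time) {
    o <- order(t)
    t <- t[o]; x <- x[o]; y <- y[o]
  }
  if (is.null(arena) && !is.null(meta$arena_side)) {
    arena <- arena_spec(side_length = as.numeric(meta$arena_side))
  }
  if (clamp && !is.null(arena)) {
    x <- pmin(pmax(x, 0), arena$side_length)
    y <- pmin(pmax(y, 0), arena$side_length)
  }
  trajectory(
    t, x, y,
    participant_id = meta$participant_id %||% "unknown",
    experiment_id = meta$experiment_id %||% "unknown",
    nominal_rate = as.numeric(meta$nominal_rate %||% 20),
    arena = arena
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a position log
#'
#' Writes a trajectory in the canonical dialect: `# key=value` metadata
#' lines, a `t_s,x_m,y_m` header, and one fixed-precision (6 decimals) row
#' per sample. [read_log()] of the result reproduces the samples to 1e-6.
#'
#' @param traj An `oft_trajectory`.
#' @param path Output file.
#' @param arena Optional [arena_spec()]; its side length is recorded in the
#'   metadata header.
#'
#' @return `path`, invisibly.
#' @export
write_log <- function(traj, path, arena = NULL) {
  stopifnot(inherits(traj, "oft_trajectory"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# participant_id=", traj$participant_id),
    paste0("# experiment_id=", traj$experiment_id),
    paste0("# nominal_rate=", format(traj$nominal_rate)),
    if (!is.null(arena)) paste0("# arena_side=", format(arena$side_length)),
    "t_s,x_m,y_m"
  ), con)
  if (length(traj$t) > 0) {
    writeLines(sprintf("%.6f,%.6f,%.6f", traj$t, traj$x, traj$y), con)
  }
  invisible(path)
}

#' Extract teleport events from a trajectory
#'
#' With teleportation locomotion the position log is a sequence of dwell
#' episodes separated by discontinuous jumps. Any consecutive-sample
#' displacement larger than `threshold` is reported as a teleport event.
#' The default threshold of 0.5 m per inter-sample step separates physical
#' micro-movements inside the tracking space (far below 0.5 m per 50 ms at
#' 20 Hz) from teleport jumps.
#'
#' @param traj An `oft_trajectory`.
#' @param threshold Displacement threshold in meters (> 0).
#'
#' @return A data.frame with one row per event: `index` (sample index of
#'   the jump's origin) and `displacement` in meters. The `displacement`
#'   column doubles as an empirical teleport-distance sample for
#'   [null_model_config()].
#' @export
extract_teleports <- function(traj, threshold = 0.5) {
  stopifnot(inherits(traj, "oft_trajectory"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single positive number", call. = FALSE)
  }
  n <- length(traj$t)
  if (n < 2) {
    return(data.frame(index = integer(0), displacement = numeric(0)))
  }
  d <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  i <- which(d > threshold)
  data.frame(index = i, displacement = d[i])
}
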