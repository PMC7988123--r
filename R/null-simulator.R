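#' Teleport-distance samplers
#'
#' The random-agent null model draws a teleport distance for every step.
#' `dist_sampler_empirical()` resamples (with replacement) from an observed
#' distance sample, e.g. the `displacement` column of
#' [extract_teleports()]. `dist_sampler_lognormal()` is a truncated
#' log-normal fallback for when no empirical sample is available; its
#' defaults (median 3 m, sigma 0.5 on the log scale, truncated to
#' 0.1-15 m) are plausible for arc-based VR teleportation, where a single
#' jump rarely exceeds a dozen meters.
#'
#' Both samplers consume exactly one uniform variate per draw, so two
#' simulations with the same seed and different samplers stay aligned on
#' the random-number stream.
#'
#' @param values Positive distances in meters (empirical sampler).
#' @param median Median teleport distance in meters.
#' @param sdlog Standard deviation on the log scale.
#' @param lo,hi Truncation bounds in meters.
#'
#' @return An object of class `oft_dist_sampler`.
#' @export
dist_sampler_lognormal <- function(median = 3, sdlog = 0.5, lo = 0.1, hi = 15) {
  stopifnot(median > 0, sdlog > 0, lo > 0, hi > lo)
  structure(list(type = "lognormal", meanlog = log(median), sdlog = sdlog,
                 lo = lo, hi = hi),
            class = "oft_dist_sampler")
}

#' @rdname dist_sampler_lognormal
#' @export
dist_sampler_empirical <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values) || any(values <= 0)) {
    stop("empirical distance sample must be non-empty and strictly positive",
         call. = FALSE)
  }
  structure(list(type = "empirical", values = values),
            class = "oft_dist_sampler")
}

sample_distance <- function(sampler, n = 1) {
  u <- stats::runif(n)
  switch(sampler$type,
    lognormal = {
      p_lo <- stats::plnorm(sampler$lo, sampler$meanlog, sampler$sdlog)
      p_hi <- stats::plnorm(sampler$hi, sampler$meanlog, sampler$sdlog)
      stats::qlnorm(p_lo + u * (p_hi - p_lo), sampler$meanlog, sampler$sdlog)
    },
    empirical = sampler$values[ceiling(u * length(sampler$values))],
    stop("unknown distance sampler type: ", sampler$type, call. = FALSE)
  )
}

oft_start_labels <- c("center_n", "center_e", "center_s", "center_w",
                      "wall_n", "wall_e", "wall_s", "wall_w")

#' Null-model configuration
#'
#' Parameters of the random teleporting agent used to derive expected
#' values for the behavioral indices: number of teleports per session
#' (default 367, the cohort median), a teleport-distance sampler, the
#' heading diffusion (a normal perturbation with mean 0 centered on the
#' current heading, sd 45 degrees), the number of simulation runs (default
#' 1000) and the eight session start positions.
#'
#' `position_sampler = "uniform"` replaces the teleport kernel with i.i.d.
#' uniform in-arena positions — a degenerate agent whose index
#' expectations have closed forms (half the session in each region, mean
#' wall distance `side / 6`), used as an analytic reference.
#'
#' @param arena An [arena_spec()].
#' @param n_teleports Teleports per simulated session.
#' @param distance_sampler An `oft_dist_sampler`.
#' @param heading_sigma Heading perturbation sd in degrees.
#' @param n_runs Number of simulation runs for [expected_values()].
#' @param start_positions Labels cycled across runs.
#' @param max_reject Consecutive out-of-arena proposals tolerated before a
#'   simulation error is raised.
#' @param seed Integer seed for [expected_values()], or `NULL`.
#' @param position_sampler `"teleport"` (default) or `"uniform"`.
#'
#' @return An object of class `oft_null_config`.
#' @export
null_model_config <- function(arena = arena_spec(), n_teleports = 367,
                              distance_sampler = dist_sampler_lognormal(),
                              heading_sigma = 45, n_runs = 1000,
                              start_positions = oft_start_labels,
                              max_reject = 10000, seed = NULL,
                              position_sampler = c("teleport", "uniform")) {
  stopifnot(inherits(arena, "oft_arena"),
            inherits(distance_sampler, "oft_dist_sampler"))
  if (n_teleports < 0 || n_teleports != round(n_teleports)) {
    stop("'n_teleports' must be a non-negative integer", call. = FALSE)
  }
  if (heading_sigma <= 0) stop("'heading_sigma' must be > 0", call. = FALSE)
  if (n_runs < 1) stop("'n_runs' must be >= 1", call. = FALSE)
  bad <- setdiff(start_positions, oft_start_labels)
  if (length(bad) > 0) {
    stop("unknown start position label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(arena = arena, n_teleports = as.integer(n_teleports),
         distance_sampler = distance_sampler,
         heading_sigma = heading_sigma, n_runs = as.integer(n_runs),
         start_positions = start_positions,
         max_reject = as.integer(max_reject), seed = seed,
         position_sampler = match.arg(position_sampler)),
    class = "oft_null_config"
  )
}

#' Session start poses
#'
#' The eight start poses: four at the arena center facing each of the four
#' walls, four at the wall midpoints (1 m inside the wall) facing the
#' center. Labels use compass-style suffixes with "n" the `+y` wall.
#'
#' @param label One of `"center_n"`, `"center_e"`, `"center_s"`,
#'   `"center_w"`, `"wall_n"`, `"wall_e"`, `"wall_s"`, `"wall_w"`.
#' @param arena An [arena_spec()].
#'
#' @return A list with `x`, `y` (meters) and `heading` (radians,
#'   counterclockwise from `+x`).
#' @export
start_pose <- function(label, arena) {
  stopifnot(inherits(arena, "oft_arena"))
  side <- arena$side_length
  half <- side / 2
  pose <- switch(label,
    center_n = list(x = half, y = half, heading = pi / 2),
    center_e = list(x = half, y = half, heading = 0),
    center_s = list(x = half, y = half, heading = -pi / 2),
    center_w = list(x = half, y = half, heading = pi),
    wall_n = list(x = half, y = side - 1, heading = -pi / 2),
    wall_e = list(x = side - 1, y = half, heading = pi),
    wall_s = list(x = half, y = 1, heading = pi / 2),
    wall_w = list(x = 1, y = half, heading = 0),
    stop("unknown start position label: ", label, call. = FALSE)
  )
  pose
}

#' One teleport step of the random agent
#'
#' Proposes a heading (current heading plus a normal perturbation with sd
#' `heading_sigma` degrees) and a distance from the configured sampler; the
#' destination is accepted iff it lies inside the arena, otherwise both
#' heading and distance are resampled. Heading is persistent: the accepted
#' proposal's heading becomes the agent's new heading.
#'
#' @param pose A list with `x`, `y`, `heading` (as from [start_pose()]).
#' @param cfg An [null_model_config()].
#'
#' @return The new pose (same shape as `pose`). Raises a simulation error
#'   after `max_reject` consecutive rejections, which signals a distance
#'   distribution incompatible with the arena.
#' @export
sim_step <- function(pose, cfg) {
  side <- cfg$arena$side_length
  sigma_rad <- cfg$heading_sigma * pi / 180
  for (i in seq_len(cfg$max_reject)) {
    heading <- pose$heading + stats::rnorm(1, 0, sigma_rad)
    d <- sample_distance(cfg$distance_sampler, 1)
    x <- pose$x + d * cos(heading)
    y <- pose$y + d * sin(heading)
    if (x >= 0 && x <= side && y >= 0 && y <= side) {
      return(list(x = x, y = y, heading = heading))
    }
  }
  stop(sprintf(
    "simulation error: %d consecutive teleport proposals rejected at (%.2f, %.2f)",
    cfg$max_reject, pose$x, pose$y), call. = FALSE)
}

# Expand teleport destinations into a constant-rate sample stream with
# (near-)equal dwell per destination; sample counts sum exactly to
# duration * rate.
expand_positions <- function(xs, ys, arena, participant_id = "sim",
                             experiment_id = "null_model") {
  n_pos <- length(xs)
  n_samp <- round(arena$session_duration * arena$sample_rate)
  pos_idx <- floor(seq_len(n_samp) * n_pos / n_samp - 1e-9) + 1L
  pos_idx <- pmin(pmax(pos_idx, 1L), n_pos)
  trajectory(
    t = (seq_len(n_samp) - 1) / arena$sample_rate,
    x = xs[pos_idx], y = ys[pos_idx],
    participant_id = participant_id, experiment_id = experiment_id,
    nominal_rate = arena$sample_rate, arena = arena
  )
}

#' Simulate one null-model session
#'
#' Runs the teleporting agent from a start pose until the configured
#' number of teleports is reached, then expands the visited positions into
#' a constant-rate position log (equal dwell time per destination) so the
#' index functions consume it exactly like a participant log.
#'
#' @param cfg An [null_model_config()].
#' @param start_label Start pose label (see [start_pose()]).
#' @param seed Optional integer seed; with a seed the run is reproducible
#'   bit for bit.
#' @param wall_bias Wall-attraction coefficient passed to [biased_step()];
#'   0 (the default) gives the unbiased null agent.
#' @param participant_id,experiment_id Metadata for the returned
#'   trajectory.
#'
#' @return An `oft_trajectory` with `session_duration * sample_rate`
#'   samples.
#' @export
simulate_run <- function(cfg, start_label = "center_n", seed = NULL,
                         wall_bias = 0, participant_id = "sim",
                         experiment_id = "null_model") {
  stopifnot(inherits(cfg, "oft_null_config"))
  if (!is.null(seed)) set.seed(seed)
  n_pos <- cfg$n_teleports + 1L
  if (cfg$position_sampler == "uniform") {
    pose <- start_pose(start_label, cfg$arena)
    xs <- c(pose$x, stats::runif(cfg$n_teleports, 0, cfg$arena$side_length))
    ys <- c(pose$y, stats::runif(cfg$n_teleports, 0, cfg$arena$side_length))
  } else {
    xs <- numeric(n_pos)
    ys <- numeric(n_pos)
    pose <- start_pose(start_label, cfg$arena)
    xs[1] <- pose$x; ys[1] <- pose$y
    for (i in seq_len(cfg$n_teleports)) {
      pose <- if (wall_bias == 0) sim_step(pose, cfg) else
        biased_step(pose, wall_bias, cfg)
      xs[i + 1] <- pose$x; ys[i + 1] <- pose$y
    }
  }
  expand_positions(xs, ys, cfg$arena, participant_id = participant_id,
                   experiment_id = experiment_id)
}

#' Expected behavioral indices under the null model
#'
#' Simulates `n_runs` sessions (start labels cycled deterministically
#' across runs), computes the full index set for each, and averages. The
#' per-index means are the references (mu) for the one-sample tests of an
#' observed cohort; Monte-Carlo standard errors accompany them.
#'
#' @param cfg An [null_model_config()]; its `seed` (required here) drives
#'   the per-run seeds.
#'
#' @return An object of class `oft_expected`: a list with `mean` and `se`
#'   (named over the numeric indices), `n_runs`, and the per-run index
#'   table in `$per_run`.
#' @export
expected_values <- function(cfg) {
  stopifnot(inherits(cfg, "oft_null_config"))
  if (is.null(cfg$seed)) {
    stop("expected_values() needs a seed in the config for reproducibility",
         call. = FALSE)
  }
  labels <- cfg$start_positions[(seq_len(cfg$n_runs) - 1) %%
                                  length(cfg$start_positions) + 1]
  grid <- bin_grid(cfg$arena)
  rows <- vector("list", cfg$n_runs)
  for (i in seq_len(cfg$n_runs)) {
    traj <- simulate_run(cfg, labels[i], seed = cfg$seed + i,
                         participant_id = sprintf("run%04d", i))
    rows[[i]] <- compute_indices(traj, cfg$arena, grid)
  }
  per_run <- do.call(rbind, rows)
  num <- vapply(per_run, is.numeric, logical(1))
  m <- colMeans(per_run[num])
  se <- vapply(per_run[num], stats::sd, numeric(1)) / sqrt(cfg$n_runs)
  structure(list(mean = m, se = se, n_runs = cfg$n_runs, per_run = per_run),
            class = "oft_expected")
}

#' @export
print.oft_expected <- function(x, ...) {
  cat(sprintf("Null-model expected values over %d runs:\n", x$n_runs))
  keys <- c("time_outer", "mean_wall_distance", "pct_thigmotaxis",
            "pct_center_entry", "pct_center_ambulation", "pct_center_leave")
  for (k in keys) {
    cat(sprintf("  %-24s %8.3f (SE %.3f)\n", k, x$mean[[k]], x$se[[k]]))
  }
  invisible(x)
}
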