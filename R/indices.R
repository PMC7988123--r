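#' Time spent in the inner and outer region
#'
#' Counts position samples per region and divides by the sample rate, so
#' with a full 900 s session at 20 Hz the two times sum to 900 s.
#'
#' @param traj An [trajectory()].
#' @param partition A [make_partition()] result.
#' @param rate Samples per second used for the count-to-time conversion;
#'   defaults to the trajectory's nominal rate.
#'
#' @return Named numeric vector `c(time_inner =, time_outer =)` in seconds.
#' @export
time_in_regions <- function(traj, partition, rate = traj$nominal_rate) {
  stopifnot(inherits(traj, "oft_trajectory"))
  if (length(traj$t) == 0) stop("empty trajectory", call. = FALSE)
  region <- classify_region(traj$x, traj$y, partition)
  c(time_inner = sum(region == "inner") / rate,
    time_outer = sum(region == "outer") / rate)
}

#' Region-wise path length and walking speed
#'
#' Total path length is the sum of Euclidean distances between consecutive
#' samples. Each inter-sample segment is assigned to the region of its
#' starting sample; region speed is region path divided by region time and
#' is reported as `NA` for an unvisited region.
#'
#' @inheritParams time_in_regions
#'
#' @return Named numeric vector with `path_inner`, `path_outer` (meters)
#'   and `speed_inner`, `speed_outer` (m/s, `NA` when the region time is
#'   zero).
#' @export
path_and_speed <- function(traj, partition, rate = traj$nominal_rate) {
  stopifnot(inherits(traj, "oft_trajectory"))
  n <- length(traj$t)
  if (n < 2) stop("need at least 2 samples for path length", call. = FALSE)
  seg <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  origin <- classify_region(traj$x[-n], traj$y[-n], partition)
  path_inner <- sum(seg[origin == "inner"])
  path_outer <- sum(seg[origin == "outer"])
  tt <- time_in_regions(traj, partition, rate)
  c(path_inner = path_inner,
    path_outer = path_outer,
    speed_inner = if (tt[["time_inner"]] > 0) path_inner / tt[["time_inner"]] else NA_real_,
    speed_outer = if (tt[["time_outer"]] > 0) path_outer / tt[["time_outer"]] else NA_real_)
}

#' Mean proximity to the wall
#'
#' Arithmetic mean of the nearest-wall distance over all samples. Under
#' uniform random occupancy of a square arena the expectation is
#' `side / 6` (16.67 m for a 100 m arena).
#'
#' @inheritParams time_in_regions
#' @param arena An [arena_spec()].
#'
#' @return Mean distance in meters, in `[0, side / 2]`.
#' @export
mean_wall_proximity <- function(traj, arena) {
  stopifnot(inherits(traj, "oft_trajectory"))
  if (length(traj$t) == 0) stop("empty trajectory", call. = FALSE)
  mean(wall_distance(traj$x, traj$y, arena))
}

crossing_classes <- c("thigmotaxis", "center_entry", "center_ambulation",
                      "center_leave")

classify_crossings <- function(origin_ring, dest_ring) {
  cls <- character(length(origin_ring))
  cls[origin_ring == "outer_ring" & dest_ring == "outer_ring"] <- "thigmotaxis"
  cls[origin_ring == "outer_ring" & dest_ring == "inner_block"] <- "center_entry"
  cls[origin_ring == "inner_block" & dest_ring == "inner_block"] <- "center_ambulation"
  cls[origin_ring == "inner_block" & dest_ring == "outer_ring"] <- "center_leave"
  cls
}

# Boundary-crossing parameters of the segment (x0,y0)->(x1,y1) against the
# grid lines, excluding the endpoints; returns sorted parameter values.
segment_grid_breaks <- function(x0, y0, x1, y1, bin_side, side) {
  breaks <- numeric(0)
  for (coords in list(c(x0, x1), c(y0, y1))) {
    a <- coords[1]; b <- coords[2]
    if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      lines_at <- bin_side * seq_len(ceiling(side / bin_side) - 1)
      hit <- lines_at[lines_at > lo & lines_at < hi]
      breaks <- c(breaks, (hit - a) / (b - a))
    }
  }
  sort(unique(breaks[breaks > 0 & breaks < 1]))
}

#' Line crossings on the bin raster
#'
#' For every pair of consecutive samples falling in different bins one
#' crossing is counted and classified by the ring of the origin and
#' destination bin: outer to outer is thigmotaxis, outer to inner a center
#' entry, inner to inner center ambulation, and inner to outer a center
#' leave. Proportions are percentages of the total crossing count.
#'
#' With teleportation locomotion a single jump can traverse several bins;
#' by default it still counts as one crossing, classified by its endpoint
#' rings only. `mode = "interpolate"` instead subdivides the straight
#' segment at every bin boundary and counts each boundary passage as its
#' own crossing.
#'
#' @param traj An [trajectory()].
#' @param grid A [bin_grid()].
#' @param mode `"endpoints"` (default) or `"interpolate"`.
#'
#' @return A list with `counts` and `proportions`, each a named numeric
#'   vector over the four crossing classes (proportions are `NA` when
#'   there are no crossings), plus `total`.
#' @export
line_crossings <- function(traj, grid, mode = c("endpoints", "interpolate")) {
  stopifnot(inherits(traj, "oft_trajectory"))
  mode <- match.arg(mode)
  counts <- stats::setNames(numeric(4), crossing_classes)
  n <- length(traj$t)
  if (n >= 2) {
    bins <- bin_of(traj$x, traj$y, grid)
    bin_id <- bins$row * grid$n_per_side + bins$col
    moved <- which(diff(bin_id) != 0)
    if (mode == "endpoints") {
      cls <- classify_crossings(bins$ring[moved], bins$ring[moved + 1])
      tab <- table(factor(cls, levels = crossing_classes))
      counts <- counts + as.numeric(tab)
    } else {
      for (i in moved) {
        br <- segment_grid_breaks(traj$x[i], traj$y[i],
                                  traj$x[i + 1], traj$y[i + 1],
                                  grid$bin_side, grid$side_length)
        mid <- (c(0, br) + c(br, 1)) / 2   # one parameter per visited bin
        px <- traj$x[i] + mid * (traj$x[i + 1] - traj$x[i])
        py <- traj$y[i] + mid * (traj$y[i + 1] - traj$y[i])
        sub <- bin_of(px, py, grid)
        sub_id <- sub$row * grid$n_per_side + sub$col
        step_moved <- which(diff(sub_id) != 0)
        cls <- classify_crossings(sub$ring[step_moved], sub$ring[step_moved + 1])
        tab <- table(factor(cls, levels = crossing_classes))
        counts <- counts + as.numeric(tab)
      }
    }
  }
  total <- sum(counts)
  proportions <- if (total > 0) 100 * counts / total else counts * NA_real_
  list(counts = counts, proportions = proportions, total = total)
}

#' Occupancy heatmap
#'
#' Grids the arena at the given resolution and accumulates, per cell, the
#' total dwell time (samples divided by the sample rate) over one or more
#' trajectories. The matrix total equals the summed trajectory durations.
#'
#' @param trajectories An `oft_trajectory` or list thereof.
#' @param arena An [arena_spec()].
#' @param resolution Cell side in meters; must divide the arena into at
#'   least 2 cells per side.
#'
#' @return A numeric matrix of dwell times in seconds; rows index y (from
#'   the origin wall), columns x.
#' @export
occupancy_heatmap <- function(trajectories, arena, resolution = 2) {
  stopifnot(inherits(arena, "oft_arena"))
  if (inherits(trajectories, "oft_trajectory")) {
    trajectories <- list(trajectories)
  }
  n_cells <- floor(arena$side_length / resolution)
  if (n_cells < 2) {
    stop("'resolution' must divide the arena into at least 2 cells per side",
         call. = FALSE)
  }
  cell <- arena$side_length / n_cells
  mat <- matrix(0, nrow = n_cells, ncol = n_cells)
  for (traj in trajectories) {
    stopifnot(inherits(traj, "oft_trajectory"))
    if (length(traj$t) == 0) next
    check_in_arena(traj$x, traj$y, arena$side_length)
    col <- pmin(floor(traj$x / cell), n_cells - 1) + 1
    row <- pmin(floor(traj$y / cell), n_cells - 1) + 1
    counts <- table(factor(row, levels = seq_len(n_cells)),
                    factor(col, levels = seq_len(n_cells)))
    mat <- mat + as.matrix(counts) / traj$nominal_rate
  }
  unname(mat)
}

#' Compute the full behavioral index set for one trajectory
#'
#' Bundles every open-field index into a single one-row data frame:
#' region times, region path lengths and speeds, mean wall proximity, and
#' the four line-crossing counts with their proportions.
#'
#' @param traj An [trajectory()].
#' @param arena An [arena_spec()].
#' @param grid Optional [bin_grid()]; defaults to the 7 x 7 raster.
#' @param mode Crossing-counting mode passed to [line_crossings()].
#'
#' @return A one-row data.frame (one column per index) carrying
#'   `participant_id` and `experiment_id`.
#' @examples
#' arena <- arena_spec()
#' cfg <- null_model_config(arena, seed = 1)
#' tr <- simulate_run(cfg, "center_n", seed = 1)
#' compute_indices(tr, arena)
#' @export
compute_indices <- function(traj, arena, grid = bin_grid(arena),
                            mode = "endpoints") {
  stopifnot(inherits(traj, "oft_trajectory"), inherits(arena, "oft_arena"))
  part <- make_partition(arena)
  tt <- time_in_regions(traj, part)
  ps <- path_and_speed(traj, part)
  lc <- line_crossings(traj, grid, mode = mode)
  out <- data.frame(
    participant_id = traj$participant_id,
    experiment_id = traj$experiment_id,
    time_inner = tt[["time_inner"]],
    time_outer = tt[["time_outer"]],
    path_inner = ps[["path_inner"]],
    path_outer = ps[["path_outer"]],
    speed_inner = ps[["speed_inner"]],
    speed_outer = ps[["speed_outer"]],
    mean_wall_distance = mean_wall_proximity(traj, arena),
    stringsAsFactors = FALSE
  )
  for (cl in crossing_classes) {
    out[[paste0("n_", cl)]] <- lc$counts[[cl]]
    out[[paste0("pct_", cl)]] <- lc$proportions[[cl]]
  }
  out$total_crossings <- lc$total
  out
}
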