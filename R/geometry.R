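#' Arena specification
#'
#' Describes the square open-field arena and the session it hosts. The
#' coordinate system has its origin at one corner of the arena with the x
#' and y axes running along the walls, so in-arena points satisfy
#' `0 <= x, y <= side_length`.
#'
#' @param side_length Side of the square arena in meters.
#' @param session_duration Session length in seconds.
#' @param sample_rate Position samples per second.
#'
#' @return An object of class `oft_arena`.
#' @examples
#' arena_spec()                  # 100 m arena, 900 s session at 20 Hz
#' arena_spec(side_length = 50)
#' @export
arena_spec <- function(side_length = 100, session_duration = 900,
                       sample_rate = 20) {
  if (!is.numeric(side_length) || length(side_length) != 1L ||
      !is.finite(side_length) || side_length <= 0) {
    stop("invalid arena: 'side_length' must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(session_duration) || length(session_duration) != 1L ||
      !is.finite(session_duration) || session_duration <= 0) {
    stop("invalid arena: 'session_duration' must be a single positive number",
         call. = FALSE)
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L ||
      !is.finite(sample_rate) || sample_rate <= 0) {
    stop("invalid arena: 'sample_rate' must be a single positive number",
         call. = FALSE)
  }
  structure(
    list(side_length = as.numeric(side_length),
         session_duration = as.numeric(session_duration),
         sample_rate = as.numeric(sample_rate)),
    class = "oft_arena"
  )
}

#' @export
print.oft_arena <- function(x, ...) {
  cat(sprintf("Open-field arena: %g m x %g m, %g s session at %g Hz\n",
              x$side_length, x$side_length, x$session_duration,
              x$sample_rate))
  invisible(x)
}

#' Equal-area inner/outer partition of the arena
#'
#' Splits the square arena into a centered inner square and a surrounding
#' outer band such that the inner region covers exactly half of the total
#' area. This forces `inner_side = side_length / sqrt(2)` and an outer band
#' of width `(side_length - inner_side) / 2`; for a 100 m arena the band is
#' 14.64 m wide.
#'
#' @param arena An [arena_spec()].
#'
#' @return An object of class `oft_partition` with fields `inner_side`,
#'   `outer_width` and `side_length`.
#' @examples
#' p <- make_partition(arena_spec())
#' p$outer_width  # 14.64 m
#' @export
make_partition <- function(arena) {
  stopifnot(inherits(arena, "oft_arena"))
  side <- arena$side_length
  inner_side <- side / sqrt(2)
  structure(
    list(side_length = side,
         inner_side = inner_side,
         outer_width = (side - inner_side) / 2),
    class = "oft_partition"
  )
}

#' @export
print.oft_partition <- function(x, ...) {
  cat(sprintf(
    "Equal-area partition of a %g m arena: inner side %.4f m, outer band %.4f m\n",
    x$side_length, x$inner_side, x$outer_width))
  invisible(x)
}

#' Bin raster for line-crossing classification
#'
#' Overlays the arena with an `n_per_side` x `n_per_side` grid of square
#' bins. Bins touching a wall form the outer ring; the remaining bins form
#' the inner block. For the default 7 x 7 raster there are 24 outer-ring and
#' 25 inner-block bins, so the two ring classes approximate the equal-area
#' inner/outer partition.
#'
#' @param arena An [arena_spec()].
#' @param n_per_side Number of bins along each side (default 7).
#'
#' @return An object of class `oft_grid` with fields `n_per_side`,
#'   `bin_side`, `side_length` and `ring`, a `n x n` character matrix of
#'   `"outer_ring"` / `"inner_block"` labels indexed `[row + 1, col + 1]`
#'   (rows and columns are counted from 0 at the origin corner).
#' @examples
#' g <- bin_grid(arena_spec())
#' g$bin_side           # 14.29 m
#' table(g$ring)        # 25 inner_block, 24 outer_ring
#' @export
bin_grid <- function(arena, n_per_side = 7) {
  stopifnot(inherits(arena, "oft_arena"))
  if (!is.numeric(n_per_side) || length(n_per_side) != 1L ||
      n_per_side < 1 || n_per_side != round(n_per_side)) {
    stop("'n_per_side' must be a single positive integer", call. = FALSE)
  }
  n <- as.integer(n_per_side)
  idx <- seq_len(n) - 1L
  on_edge <- outer(idx %in% c(0L, n - 1L), idx %in% c(0L, n - 1L), `|`)
  ring <- ifelse(on_edge, "outer_ring", "inner_block")
  structure(
    list(n_per_side = n,
         bin_side = arena$side_length / n,
         side_length = arena$side_length,
         ring = ring),
    class = "oft_grid"
  )
}

check_in_arena <- function(x, y, side) {
  bad <- !is.finite(x) | !is.finite(y) | x < 0 | y < 0 | x > side | y > side
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "out of bounds: point (%g, %g) lies outside the %g m arena",
      x[i], y[i], side), call. = FALSE)
  }
  invisible(TRUE)
}

#' Classify points into the inner or outer region
#'
#' A point belongs to the inner region iff it lies in the closed centered
#' square of side `inner_side`; points exactly on the inner boundary count
#' as inner. Vectorized over coordinates.
#'
#' @param x,y Point coordinates in meters.
#' @param partition An [make_partition()] result.
#'
#' @return Character vector of `"inner"` / `"outer"`.
#' @examples
#' p <- make_partition(arena_spec())
#' classify_region(c(50, 1), c(50, 50), p)  # "inner" "outer"
#' @export
classify_region <- function(x, y, partition) {
  stopifnot(inherits(partition, "oft_partition"))
  check_in_arena(x, y, partition$side_length)
  half <- partition$inner_side / 2
  c0 <- partition$side_length / 2
  inner <- abs(x - c0) <= half & abs(y - c0) <= half
  ifelse(inner, "inner", "outer")
}

#' Distance to the nearest wall
#'
#' For an in-arena point the nearest-wall distance is
#' `min(x, side - x, y, side - y)`, ranging from 0 at a wall to `side / 2`
#' at the center. Vectorized over coordinates.
#'
#' @inheritParams classify_region
#' @param arena An [arena_spec()].
#'
#' @return Numeric vector of distances in meters.
#' @examples
#' wall_distance(c(50, 10, 0), c(50, 30, 42), arena_spec())  # 50 10 0
#' @export
wall_distance <- function(x, y, arena) {
  stopifnot(inherits(arena, "oft_arena"))
  side <- arena$side_length
  check_in_arena(x, y, side)
  pmin(x, side - x, y, side - y)
}

#' Locate points on the bin raster
#'
#' Bins are addressed by `floor`-division of the coordinates by the bin
#' side; rows and columns are counted from 0 at the origin corner, and a
#' coordinate equal to `side_length` is clamped into the last bin so the
#' top and right walls belong to the raster. The ring label is
#' `"outer_ring"` iff the row or column index is 0 or `n - 1`.
#'
#' @inheritParams classify_region
#' @param grid A [bin_grid()].
#'
#' @return A data.frame with columns `row`, `col` (0-based integers) and
#'   `ring`.
#' @examples
#' g <- bin_grid(arena_spec())
#' bin_of(c(0.1, 50, 100), c(0.1, 50, 100), g)
#' @export
bin_of <- function(x, y, grid) {
  stopifnot(inherits(grid, "oft_grid"))
  check_in_arena(x, y, grid$side_length)
  n <- grid$n_per_side
  col <- pmin(floor(x / grid$bin_side), n - 1)
  row <- pmin(floor(y / grid$bin_side), n - 1)
  edge <- row == 0 | row == n - 1 | col == 0 | col == n - 1
  data.frame(row = as.integer(row), col = as.integer(col),
             ring = ifelse(edge, "outer_ring", "inner_block"),
             stringsAsFactors = FALSE)
}
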