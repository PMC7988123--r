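arena <- arena_spec()
part <- make_partition(arena)
grid <- bin_grid(arena)

test_that("region times are sample counts over the rate", {
  center <- toy_traj(rep(50, 18000), rep(50, 18000))
  expect_equal(time_in_regions(center, part),
               c(time_inner = 900, time_outer = 0))

  corner <- toy_traj(rep(1, 18000), rep(1, 18000))
  expect_equal(time_in_regions(corner, part),
               c(time_inner = 0, time_outer = 900))

  # 6-sample toy path, 4 outer + 2 inner, classified by the geometry oracle
  x <- c(1, 2, 50, 50, 99, 98)
  y <- c(1, 2, 50, 51, 99, 98)
  oracle_inner <- sum(vapply(seq_along(x), function(i) {
    w <- min(x[i], 100 - x[i], y[i], 100 - y[i])
    w >= part$outer_width
  }, logical(1)))
  tt <- time_in_regions(toy_traj(x, y), part)
  expect_equal(unname(tt[["time_inner"]]), oracle_inner / 20)
  expect_equal(tt, c(time_inner = 0.1, time_outer = 0.2))

  expect_error(time_in_regions(toy_traj(numeric(0), numeric(0)), part),
               "empty")
})

test_that("path length splits by origin region and speeds divide by region time", {
  # straight 10 m walk inside the inner region over 10 s
  walk <- trajectory(t = 0:10, x = seq(45, 55, by = 1), y = rep(50, 11),
                     nominal_rate = 1)
  ps <- path_and_speed(walk, part)
  expect_equal(unname(ps[["path_inner"]]), 10)
  expect_equal(unname(ps[["path_outer"]]), 0)
  expect_equal(unname(ps[["speed_inner"]]), 10 / 11)  # 11 samples at 1 Hz
  expect_true(is.na(ps[["speed_outer"]]))

  two <- toy_traj(c(10, 13), c(20, 20))
  ps2 <- path_and_speed(two, part)
  expect_equal(unname(ps2[["path_inner"]] + ps2[["path_outer"]]), 3)

  # toy path crossing the partition: per-segment brute-force sums
  set.seed(5)
  x <- runif(40, 0, 100); y <- runif(40, 0, 100)
  tr <- toy_traj(x, y)
  ps3 <- path_and_speed(tr, part)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  inner_o <- vapply(seq_len(39), function(i) {
    min(x[i], 100 - x[i], y[i], 100 - y[i]) >= part$outer_width
  }, logical(1))
  expect_equal(unname(ps3[["path_inner"]]), sum(seg[inner_o]))
  expect_equal(unname(ps3[["path_outer"]]), sum(seg[!inner_o]))
  expect_error(path_and_speed(toy_traj(1, 1), part), "at least 2")
})

test_that("mean wall proximity averages per-sample distances", {
  expect_equal(mean_wall_proximity(toy_traj(rep(50, 10), rep(50, 10)), arena),
               50)
  half <- toy_traj(c(rep(50, 10), rep(0, 10)), rep(50, 20))
  expect_equal(mean_wall_proximity(half, arena), 25)

  set.seed(13)
  u <- toy_traj(runif(1000, 0, 100), runif(1000, 0, 100))
  se <- 100 / 6 / sqrt(1000)  # generous MC bound; sd(wall dist) < mean
  expect_lt(abs(mean_wall_proximity(u, arena) - 100 / 6), 4 * se)
})

test_that("crossing classes follow origin/destination rings", {
  one_bin <- toy_traj(c(2, 3, 2.5), c(2, 3, 2.2))
  lc0 <- line_crossings(one_bin, grid)
  expect_equal(unname(lc0$total), 0)
  expect_true(all(is.na(lc0$proportions)))

  # bin centers (0,0) -> (0,1) -> (1,1): outer->outer then outer->inner
  b <- grid$bin_side
  centers_x <- c(0.5, 1.5, 1.5) * b
  centers_y <- c(0.5, 0.5, 1.5) * b
  # (0,0) -> (0,1) is outer -> outer, (0,1) -> (1,1) is outer -> inner
  lc <- line_crossings(toy_traj(centers_x, centers_y), grid)
  expect_equal(unname(lc$counts["thigmotaxis"]), 1)
  expect_equal(unname(lc$counts["center_entry"]), 1)
  expect_equal(unname(lc$counts["center_ambulation"]), 0)
  expect_equal(unname(lc$counts["center_leave"]), 0)
})

test_that("crossing counts match the pairwise enumeration oracle on random paths", {
  set.seed(17)
  for (rep in 1:100) {
    m <- sample(3:12, 1)
    x <- runif(m, 0, 100); y <- runif(m, 0, 100)
    lc <- line_crossings(toy_traj(x, y), grid)
    expect_equal(unname(lc$counts), unname(oracle_line_crossings(x, y, 100, 7)))
    if (lc$total > 0) {
      expect_equal(unname(sum(lc$proportions)), 100, tolerance = 1e-9)
    }
    # entry/leave parity
    expect_lte(abs(lc$counts[["center_entry"]] - lc$counts[["center_leave"]]), 1)
  }
})

test_that("closed paths balance entries and leaves exactly", {
  set.seed(19)
  for (rep in 1:20) {
    x <- runif(8, 0, 100); y <- runif(8, 0, 100)
    x <- c(x, x[1]); y <- c(y, y[1])
    lc <- line_crossings(toy_traj(x, y), grid)
    expect_equal(unname(lc$counts[["center_entry"]]),
                 unname(lc$counts[["center_leave"]]))
  }
})

test_that("interpolation mode counts every traversed boundary", {
  # straight jump across the whole arena at y = 5: 6 boundary passages,
  # all within the bottom outer row
  jump <- toy_traj(c(5, 95), c(5, 5))
  lc_end <- line_crossings(jump, grid)
  expect_equal(unname(lc_end$total), 1)
  lc_int <- line_crossings(jump, grid, mode = "interpolate")
  expect_equal(unname(lc_int$counts[["thigmotaxis"]]), 6)
  expect_equal(unname(lc_int$total), 6)

  # an oblique jump through the center picks up entries and leaves
  # symmetrically and crosses both vertical and horizontal boundaries
  diag_tr <- toy_traj(c(5, 95), c(10, 90))
  lc_d <- line_crossings(diag_tr, grid, mode = "interpolate")
  expect_equal(unname(lc_d$counts[["center_entry"]]),
               unname(lc_d$counts[["center_leave"]]))
  expect_equal(unname(lc_d$total), 12)
})

test_that("all indices are invariant under the arena's 8 symmetries", {
  set.seed(23)
  x <- runif(60, 0, 100); y <- runif(60, 0, 100)
  base <- compute_indices(toy_traj(x, y), arena)
  syms <- list(
    function(x, y) list(x = y, y = 100 - x),        # rotate 90
    function(x, y) list(x = 100 - x, y = 100 - y),  # rotate 180
    function(x, y) list(x = 100 - y, y = x),        # rotate 270
    function(x, y) list(x = 100 - x, y = y),        # mirror x
    function(x, y) list(x = x, y = 100 - y),        # mirror y
    function(x, y) list(x = y, y = x),              # transpose
    function(x, y) list(x = 100 - y, y = 100 - x)   # anti-transpose
  )
  num <- vapply(base, is.numeric, logical(1))
  for (s in syms) {
    p <- s(x, y)
    got <- compute_indices(toy_traj(p$x, p$y), arena)
    expect_equal(got[num], base[num], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("occupancy heatmap conserves dwell time", {
  still <- toy_traj(rep(3, 18000), rep(97, 18000))
  hm <- occupancy_heatmap(still, arena, resolution = 2)
  expect_equal(sum(hm), 900)
  expect_equal(sum(hm > 0), 1)
  expect_equal(max(hm), 900)

  set.seed(29)
  trs <- list(toy_traj(runif(500, 0, 100), runif(500, 0, 100)),
              toy_traj(runif(300, 0, 100), runif(300, 0, 100)))
  hm2 <- occupancy_heatmap(trs, arena, resolution = 10)
  expect_equal(sum(hm2), (500 + 300) / 20)

  # uniform cohort is approximately uniform at coarse resolution
  set.seed(31)
  big <- toy_traj(runif(20000, 0, 100), runif(20000, 0, 100))
  hm3 <- occupancy_heatmap(big, arena, resolution = 25)
  counts <- hm3 * 20
  chisq <- sum((counts - mean(counts))^2 / mean(counts))
  expect_lt(chisq, qchisq(0.999, df = 15))

  expect_error(occupancy_heatmap(still, arena, resolution = 80),
               "at least 2 cells")
})
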