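# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive geometry from first principles (explicit
# rectangles, pairwise enumeration) rather than calling the package's own
# vectorized code paths.

# Enumerate all n x n bin rectangles and test point membership directly.
# Bin (r, c) covers [c*b, (c+1)*b) x [r*b, (r+1)*b), with the upper edge
# closed for the last row/column so the far walls belong to the raster.
oracle_bin_of <- function(x, y, side, n) {
  b <- side / n
  for (r in 0:(n - 1)) {
    for (cc in 0:(n - 1)) {
      x_hi <- if (cc == n - 1) x <= (cc + 1) * b else x < (cc + 1) * b
      y_hi <- if (r == n - 1) y <= (r + 1) * b else y < (r + 1) * b
      if (x >= cc * b && x_hi && y >= r * b && y_hi) {
        ring <- if (r %in% c(0, n - 1) || cc %in% c(0, n - 1))
          "outer_ring" else "inner_block"
        return(list(row = r, col = cc, ring = ring))
      }
    }
  }
  stop("oracle: point not in any bin")
}

# Pairwise enumeration of crossings: walk consecutive sample pairs and
# tally origin/destination ring combinations via the rectangle oracle.
oracle_line_crossings <- function(x, y, side, n) {
  counts <- c(thigmotaxis = 0, center_entry = 0, center_ambulation = 0,
              center_leave = 0)
  for (i in seq_len(length(x) - 1)) {
    a <- oracle_bin_of(x[i], y[i], side, n)
    b <- oracle_bin_of(x[i + 1], y[i + 1], side, n)
    if (a$row == b$row && a$col == b$col) next
    key <- if (a$ring == "outer_ring" && b$ring == "outer_ring")
      "thigmotaxis"
    else if (a$ring == "outer_ring") "center_entry"
    else if (b$ring == "inner_block") "center_ambulation"
    else "center_leave"
    counts[key] <- counts[key] + 1
  }
  counts
}

# Repeated-measures SS decomposition through the stock aov() Error() route.
oracle_rm_anova <- function(X) {
  long <- data.frame(
    y = as.vector(X),
    subject = factor(rep(seq_len(nrow(X)), ncol(X))),
    level = factor(rep(seq_len(ncol(X)), each = nrow(X)))
  )
  fit <- summary(stats::aov(y ~ level + Error(subject / level), data = long))
  tab <- fit[["Error: subject:level"]][[1]]
  list(f = tab["level", "F value"], p = tab["level", "Pr(>F)"],
       ss_effect = tab["level", "Sum Sq"],
       ss_error = tab["Residuals", "Sum Sq"])
}

# A trajectory visiting given points at a fixed rate.
toy_traj <- function(x, y, rate = 20, id = "toy") {
  trajectory(t = (seq_along(x) - 1) / rate, x = x, y = y,
             participant_id = id, nominal_rate = rate)
}

# Small fast null config for pipeline-level tests.
fast_null_config <- function(..., n_teleports = 80, n_runs = 16, seed = 7) {
  null_model_config(arena_spec(), n_teleports = n_teleports,
                    n_runs = n_runs, seed = seed, ...)
}
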