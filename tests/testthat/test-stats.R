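test_that("one-sample t reproduces stats::t.test and the d = t/sqrt(n) identity", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    x <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    mu <- runif(1, -1, 1)
    res <- one_sample_t(x, mu)
    ref <- t.test(x, mu = mu)
    expect_equal(res$statistic, unname(ref$statistic))
    expect_equal(res$p, ref$p.value)
    expect_equal(res$df, unname(ref$parameter))
    expect_equal(res$effect_size, res$statistic / sqrt(n))
    expect_true(res$effect_ci[1] <= res$effect_size)
    expect_true(res$effect_ci[2] >= res$effect_size)
  }
})

test_that("degenerate and trivial one-sample inputs behave as contracted", {
  expect_error(one_sample_t(rep(3, 10), 3), "degenerate")
  x <- c(1, 2, 3, 4, 5)
  res <- one_sample_t(x, mean(x))
  expect_equal(res$statistic, 0)
  expect_equal(res$effect_size, 0)
  expect_equal(res$p, 1)
  expect_equal(res$effect_ci[1], -res$effect_ci[2], tolerance = 1e-4)
  expect_error(one_sample_t(c(1), 0), "at least 2")
})

test_that("effect sizes and their noncentral-t intervals match the published examples", {
  expect_equal(round(cohens_d_from_t(3.28, 31), 2), 0.59)
  expect_equal(round(cohens_d_from_t(6.42, 30), 2), 1.17)
  expect_equal(cohens_d_from_t(0, 12), 0)

  expect_equal(round(suppressWarnings(d_confidence_interval(3.28, 31)), 2),
               c(0.20, 0.97))
  expect_equal(round(suppressWarnings(d_confidence_interval(6.42, 30)), 2),
               c(0.70, 1.63))

  # a sample engineered to t = 3.28 at n = 31 yields d = 0.59
  set.seed(4)
  x <- as.vector(scale(rnorm(31)))          # mean 0, sd 1
  x <- x + 3.28 / sqrt(31)                  # shifts t to exactly 3.28
  res <- one_sample_t(x, 0)
  expect_equal(res$statistic, 3.28, tolerance = 1e-10)
  expect_equal(round(res$effect_size, 2), 0.59)
  expect_equal(round(res$effect_ci, 2), c(0.20, 0.97))
})

test_that("d interval endpoints increase with t", {
  ts <- c(-2, 0, 1, 3, 5)
  ci <- t(vapply(ts, function(t) suppressWarnings(
    d_confidence_interval(t, 25)), numeric(2)))
  expect_true(all(diff(ci[, 1]) > 0))
  expect_true(all(diff(ci[, 2]) > 0))
})

test_that("paired t equals the one-sample t on differences", {
  set.seed(6)
  x <- rnorm(20); y <- rnorm(20)
  res <- paired_t(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)

  # direction follows the shift once noise is present
  y2 <- x - 1 + rnorm(20, sd = 0.1)
  expect_gt(paired_t(x, y2)$effect_size, 0)

  expect_error(paired_t(x, x), "degenerate")
  expect_error(paired_t(x, y[1:10]), "equal length")

  # incomplete pairs are dropped
  x[3] <- NA
  expect_equal(paired_t(x, y)$n, 19)
})

test_that("pearson correlation handles direction, identity and degeneracy", {
  x <- 1:10
  expect_equal(pearson_r(x, x)$r, 1)
  set.seed(10)
  y <- -x + rnorm(10, sd = 0.5)
  expect_lt(pearson_r(x, y)$r, 0)
  expect_error(pearson_r(x, rep(2, 10)), "degenerate")
  ref <- cor.test(x, y)
  got <- pearson_r(x, y)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
})

test_that("Bonferroni thresholds divide alpha by the test count", {
  expect_equal(round(bonferroni_threshold(0.05, 24), 3), 0.002)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
})

test_that("sign-count chi-squared matches the closed form and is symmetric", {
  res <- sign_count_chisq(46, 72)
  expect_equal(round(res$statistic, 2), 5.56)
  expect_equal(round(res$p, 3), 0.018)

  expect_equal(sign_count_chisq(36, 72)$statistic, 0)
  expect_equal(sign_count_chisq(36, 72)$p, 1)
  expect_equal(sign_count_chisq(72, 72)$statistic, 72)

  for (k in 0:20) {
    expect_equal(sign_count_chisq(k, 20)$statistic,
                 sign_count_chisq(20 - k, 20)$statistic)
  }
  # agrees with the stock goodness-of-fit test
  ref <- chisq.test(c(46, 26), p = c(0.5, 0.5))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
})

test_that("partial eta-squared from F matches the algebraic identity", {
  expect_equal(round(partial_eta_sq_from_f(1.13, 1.51, 43.83), 2), 0.04)
  expect_equal(partial_eta_sq_from_f(0, 2, 30), 0)
  # invariant under common df rescaling (the GG correction)
  eps <- 0.73
  expect_equal(partial_eta_sq_from_f(2.4, 2, 58),
               partial_eta_sq_from_f(2.4, eps * 2, eps * 58))
})

test_that("repeated-measures ANOVA matches anova.mlm with and without GG", {
  set.seed(12)
  for (rep in 1:5) {
    n <- sample(15:40, 1); k <- sample(3:5, 1)
    X <- matrix(rnorm(n * k), n, k) + rnorm(n)
    X[, 2] <- X[, 2] * runif(1, 1, 2.5) + runif(1, -1, 1)

    res <- rm_anova_gg(X, force_gg = TRUE)
    mlm <- stats::lm(X ~ 1)
    idata <- data.frame(lev = factor(seq_len(k)))
    av <- stats::anova(mlm, idata = idata, X = ~1, test = "Spherical")
    expect_equal(res$statistic, av[1, "F"], tolerance = 1e-10)
    # the G-G Pr column depends on epsilon, so matching it validates the
    # Greenhouse-Geisser estimate as well
    expect_equal(res$p, av[1, "G-G Pr"], tolerance = 1e-10)
    mt <- stats::mauchly.test(mlm, X = ~1)
    expect_equal(res$mauchly_w, unname(mt$statistic), tolerance = 1e-10)
    expect_equal(res$mauchly_p, mt$p.value, tolerance = 1e-10)
  }
})

test_that("repeated-measures ANOVA matches the aov() SS decomposition", {
  set.seed(14)
  X <- matrix(rnorm(24 * 3, sd = 2), 24, 3) + rnorm(24) +
    matrix(rep(c(0, 0.8, 0.3), each = 24), 24, 3)
  res <- rm_anova_gg(X)
  want <- oracle_rm_anova(X)
  expect_equal(res$statistic, want$f, tolerance = 1e-10)
  expect_equal(res$ss_effect, want$ss_effect, tolerance = 1e-10)
  expect_equal(res$ss_error, want$ss_error, tolerance = 1e-10)
  if (!res$gg_applied) expect_equal(res$p, want$p, tolerance = 1e-10)
  expect_equal(res$effect_size,
               want$ss_effect / (want$ss_effect + want$ss_error))
})

test_that("ANOVA degenerate and boundary cases follow the contracts", {
  # identical columns plus subject offsets: no effect at all
  off <- rnorm(10)
  X <- matrix(off, 10, 3)
  res <- rm_anova_gg(X)
  expect_equal(res$statistic, 0)
  expect_equal(res$effect_size, 0)
  expect_equal(res$p, 1)

  # listwise exclusion and the insufficient-data error
  set.seed(16)
  X <- matrix(rnorm(30), 10, 3)
  X[4, 2] <- NA
  expect_equal(rm_anova_gg(X)$n, 9)
  expect_error(rm_anova_gg(X[1:4, ]), "insufficient data")

  # epsilon bounds
  set.seed(18)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    X <- matrix(rnorm(20 * k), 20, k)
    X[, 1] <- X[, 1] * 3
    eps <- rm_anova_gg(X, force_gg = TRUE)$epsilon
    expect_gte(eps, 1 / (k - 1) - 1e-12)
    expect_lte(eps, 1 + 1e-12)
  }

  # exactly spherical contrast covariance gives epsilon = 1
  n <- 20; k <- 4
  set.seed(20)
  Z <- matrix(rnorm(n * (k - 1)), n, k - 1)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- qr.Q(qr(Z)) * sqrt(n - 1)     # contrast scores with covariance I
  C <- contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  X <- Z %*% t(C) + rnorm(n)
  expect_equal(rm_anova_gg(X, force_gg = TRUE)$epsilon, 1, tolerance = 1e-10)
})

test_that("eta-squared confidence limits bracket the point estimate", {
  set.seed(22)
  for (rep in 1:10) {
    f <- runif(1, 0.1, 8); df1 <- runif(1, 1, 4); df2 <- runif(1, 20, 120)
    ci <- partial_eta_sq_ci(f, df1, df2)
    expect_true(ci[1] >= 0 && ci[2] <= 1)
    expect_lte(ci[1], partial_eta_sq_from_f(f, df1, df2) + 1e-12)
  }
  # large F: the interval excludes zero
  ci <- partial_eta_sq_ci(12, 2, 60)
  expect_gt(ci[1], 0)
})
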