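#' @title Statistical results container
#' @description Internal constructor for the common result shape: a test
#'   statistic with degrees of freedom, p-value, effect size and an
#'   effect-size confidence interval.
#' @noRd
oft_stat <- function(method, statistic, df, p, effect_size, effect_ci,
                     conf_level, n, ...) {
  structure(
    c(list(method = method, statistic = statistic, df = df, p = p,
           effect_size = effect_size, effect_ci = effect_ci,
           conf_level = conf_level, n = n), list(...)),
    class = "oft_stat"
  )
}

#' @export
print.oft_stat <- function(x, ...) {
  dftxt <- paste(format(round(unlist(x$df), 2)), collapse = ", ")
  cat(sprintf("%s: statistic = %.3f, df = (%s), p = %.4g\n",
              x$method, x$statistic, dftxt, x$p))
  cat(sprintf("  effect size = %.3f, %d%% CI [%.3f, %.3f], n = %d\n",
              x$effect_size, round(100 * x$conf_level),
              x$effect_ci[1], x$effect_ci[2], x$n))
  invisible(x)
}

#' Cohen's d from a one-sample or paired t statistic
#'
#' Under the one-sample (and paired-difference) convention
#' `d = (mean - mu) / sd = t / sqrt(n)`.
#'
#' @param t Observed t statistic.
#' @param n Sample size (pairs for a paired design).
#'
#' @return Cohen's d.
#' @examples
#' cohens_d_from_t(3.28, 31)  # 0.59
#' cohens_d_from_t(6.42, 30)  # 1.17
#' @export
cohens_d_from_t <- function(t, n) {
  stopifnot(n >= 2)
  t / sqrt(n)
}

# Invert the noncentral-t CDF in its noncentrality parameter: find ncp such
# that pt(t, df, ncp) = target. pt() is strictly decreasing in ncp.
ncp_t_root <- function(t, df, target, tol = 1e-8) {
  # pt() warns that the noncentral tail is only accurate to ~1e-12, far
  # below the bisection tolerance; silence it
  f <- function(ncp) suppressWarnings(stats::pt(t, df, ncp = ncp)) - target
  half <- abs(t) + 10
  lo <- t - half
  hi <- t + half
  while (f(lo) < 0) { half <- 2 * half; lo <- t - half }
  while (f(hi) > 0) { half <- 2 * half; hi <- t + half }
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

#' Noncentral-t confidence interval for Cohen's d
#'
#' Pivots the noncentral-t distribution: the limits are the noncentrality
#' parameters whose CDF at the observed t equals `(1 - level) / 2` and
#' `1 - (1 - level) / 2`, divided by `sqrt(n)`.
#'
#' @param t Observed t statistic.
#' @param n Sample size.
#' @param level Confidence level (default 0.95).
#'
#' @return Numeric vector `c(lower, upper)` on the d scale.
#' @examples
#' d_confidence_interval(3.28, 31)  # about [0.20, 0.97]
#' @export
d_confidence_interval <- function(t, n, level = 0.95) {
  stopifnot(n >= 2, level > 0, level < 1)
  alpha <- 1 - level
  df <- n - 1
  lo <- ncp_t_root(t, df, 1 - alpha / 2)
  hi <- ncp_t_root(t, df, alpha / 2)
  c(lo, hi) / sqrt(n)
}

#' One-sample t-test with Cohen's d and its noncentral-t CI
#'
#' Tests the sample mean against a reference value `mu` (two-sided) and
#' reports the standardized mean difference `d = (mean - mu) / sd` with a
#' noncentral-t confidence interval. This is the test used to compare each
#' behavioral index of an observed cohort against its null-model
#' expectation.
#'
#' @param x Numeric sample (missing values dropped).
#' @param mu Reference value.
#' @param conf_level Confidence level for the d interval (default 0.95).
#'
#' @return An `oft_stat` with fields `statistic` (t), `df`, `p`,
#'   `effect_size` (d), `effect_ci`, `n`.
#' @export
one_sample_t <- function(x, mu = 0, conf_level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 non-missing observations", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in sample", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) {
    stop("degenerate sample: zero variance, t statistic undefined",
         call. = FALSE)
  }
  t <- (mean(x) - mu) * sqrt(n) / s
  df <- n - 1
  p <- 2 * stats::pt(-abs(t), df)
  oft_stat("one-sample t", statistic = t, df = df, p = p,
           effect_size = cohens_d_from_t(t, n),
           effect_ci = d_confidence_interval(t, n, conf_level),
           conf_level = conf_level, n = n, mu = mu)
}

#' Paired t-test
#'
#' One-sample t-test of the pairwise differences `x - y` against 0;
#' incomplete pairs are dropped.
#'
#' @param x,y Numeric vectors of equal length.
#' @inheritParams one_sample_t
#'
#' @return An `oft_stat` (see [one_sample_t()]).
#' @export
paired_t <- function(x, y, conf_level = 0.95) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  res <- one_sample_t(x[keep] - y[keep], mu = 0, conf_level = conf_level)
  res$method <- "paired t"
  res
}

#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation on pairwise-complete observations, with the
#' usual t-based two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length.
#'
#' @return A list with `r`, `p` and `n` (complete pairs).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have equal length", call. = FALSE)
  }
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate input: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Experiment-wise alpha.
#' @param m Number of tests.
#'
#' @return `alpha / m`; e.g. `0.05 / 24 = 0.002` (3 dp) for a 24-cell
#'   correlation table.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}

#' Sign-count chi-squared test against an equal split
#'
#' Goodness-of-fit test of `k` successes out of `n` against the 50/50
#' null: `chi^2 = (2k - n)^2 / n` on 1 df, upper-tail p. Used to ask
#' whether more correlation coefficients point in the center-avoidance
#' direction than chance would produce.
#'
#' @param k Number of coefficients in the tested direction.
#' @param n Total number of coefficients.
#'
#' @return A list with `statistic`, `df`, `p`, `k`, `n`.
#' @examples
#' sign_count_chisq(46, 72)  # chi^2 = 5.56, p = .018
#' @export
sign_count_chisq <- function(k, n) {
  stopifnot(n >= 1, k >= 0, k <= n)
  stat <- (2 * k - n)^2 / n
  list(statistic = stat, df = 1,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       k = k, n = n)
}

#' Partial eta-squared from an F statistic
#'
#' `eta_p^2 = F * df1 / (F * df1 + df2)`; algebraically invariant to a
#' common rescaling of both degrees of freedom, hence unchanged by the
#' Greenhouse-Geisser correction.
#'
#' @param f Observed F.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#'
#' @return Partial eta-squared in `[0, 1)`.
#' @examples
#' partial_eta_sq_from_f(1.13, 1.51, 43.83)  # 0.04
#' @export
partial_eta_sq_from_f <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 > 0, df2 > 0)
  f * df1 / (f * df1 + df2)
}

# Noncentrality limits of the noncentral-F distribution at the observed F;
# lower limit is 0 when even a central F exceeds the observed value with
# probability > 1 - alpha/2 tail mass.
ncp_f_limits <- function(f, df1, df2, level = 0.90, tol = 1e-8) {
  alpha <- 1 - level
  p_central <- stats::pf(f, df1, df2)
  root <- function(target) {
    g <- function(ncp) stats::pf(f, df1, df2, ncp = ncp) - target
    hi <- max(f * df1, 1) + 10
    while (g(hi) > 0) hi <- 2 * hi
    stats::uniroot(g, c(0, hi), tol = tol)$root
  }
  lo <- if (p_central < 1 - alpha / 2) 0 else root(1 - alpha / 2)
  hi <- if (p_central < alpha / 2) 0 else root(alpha / 2)
  c(lo, hi)
}

#' Confidence interval for partial eta-squared
#'
#' Noncentral-F pivot: the noncentrality limits at the observed F are
#' converted to the partial-variance-accounted-for scale via
#' `lambda / (lambda + df1 + df2 + 1)`. The conventional level for
#' eta-squared intervals is 90% (a two-sided 90% interval matches the
#' one-sided 5% F test).
#'
#' @inheritParams partial_eta_sq_from_f
#' @param level Confidence level (default 0.90).
#'
#' @return Numeric vector `c(lower, upper)`.
#' @export
partial_eta_sq_ci <- function(f, df1, df2, level = 0.90) {
  lims <- ncp_f_limits(f, df1, df2, level = level)
  lims / (lims + df1 + df2 + 1)
}

# Orthonormal contrast matrix: (k-1) rows orthogonal to the unit vector.
orthonormal_contrasts <- function(k) {
  C <- stats::contr.helmert(k)            # k x (k-1)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  t(C)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject one-way ANOVA on a subjects-by-levels matrix. Rows with
#' any missing level are excluded listwise. Sphericity is assessed with
#' Mauchly's test; when it is rejected at `sphericity_alpha` (or when
#' `force_gg = TRUE`) both degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the sample covariance of the
#' levels, and the p-value uses the corrected degrees of freedom. Partial
#' eta-squared and its noncentral-F confidence interval accompany the
#' test.
#'
#' @param data Numeric matrix or data.frame, one row per subject, one
#'   column per within-subject level (k >= 2).
#' @param force_gg Always apply the Greenhouse-Geisser correction,
#'   regardless of Mauchly's test.
#' @param sphericity_alpha Alpha for Mauchly's test (default 0.05).
#' @param eta_level Confidence level for the partial eta-squared interval
#'   (default 0.90).
#'
#' @return An `oft_stat` with `statistic` (F), `df` (a length-2 vector,
#'   corrected when applicable), `p`, `effect_size` (partial eta-squared),
#'   `effect_ci`, plus `epsilon`, `mauchly_w`, `mauchly_p`,
#'   `gg_applied`, `df_uncorrected` and `n` (subjects analyzed).
#' @export
rm_anova_gg <- function(data, force_gg = FALSE, sphericity_alpha = 0.05,
                        eta_level = 0.90) {
  X <- as.matrix(data)
  if (!is.numeric(X) || ncol(X) < 2) {
    stop("'data' must be a numeric matrix with at least 2 columns",
         call. = FALSE)
  }
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  k <- ncol(X)
  if (n <= k) {
    stop(sprintf(
      "insufficient data: %d complete subjects for %d levels", n, k),
      call. = FALSE)
  }

  grand <- mean(X)
  col_m <- colMeans(X)
  row_m <- rowMeans(X)
  ss_effect <- n * sum((col_m - grand)^2)
  resid <- X - outer(row_m, rep(1, k)) -
    outer(rep(1, n), col_m) + grand
  ss_error <- sum(resid^2)
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  if (ss_effect > 0 && ss_error == 0) {
    stop("degenerate data: zero within-subject error variance",
         call. = FALSE)
  }
  f <- if (ss_effect == 0) 0 else (ss_effect / df1) / (ss_error / df2)

  Ct <- orthonormal_contrasts(k)
  M <- Ct %*% stats::cov(X) %*% t(Ct)
  eps <- if (sum(M^2) > 0) sum(diag(M))^2 / (df1 * sum(M^2)) else 1

  # Mauchly's sphericity test on the contrast covariance, with Box's
  # second-order chi-squared correction
  if (k > 2 && det(M) > 0) {
    pp <- df1
    nn <- n - 1
    logW <- log(det(M)) - pp * log(sum(diag(M)) / pp)
    W <- exp(logW)
    rho <- 1 - (2 * pp^2 + pp + 2) / (6 * pp * nn)
    w2 <- (pp + 2) * (pp - 1) * (pp - 2) * (2 * pp^3 + 6 * pp^2 + 3 * k + 2) /
      (288 * (nn * pp * rho)^2)
    z <- -nn * rho * logW
    mdf <- pp * (pp + 1) / 2 - 1
    pr1 <- stats::pchisq(z, mdf, lower.tail = FALSE)
    pr2 <- stats::pchisq(z, mdf + 4, lower.tail = FALSE)
    mauchly_p <- pr1 + w2 * (pr2 - pr1)
  } else {
    W <- 1
    mauchly_p <- 1     # sphericity is vacuous with a single contrast
  }

  gg_applied <- force_gg || mauchly_p < sphericity_alpha
  df_use <- if (gg_applied) c(eps * df1, eps * df2) else c(df1, df2)
  p <- stats::pf(f, df_use[1], df_use[2], lower.tail = FALSE)
  eta <- if (ss_effect == 0) 0 else ss_effect / (ss_effect + ss_error)

  oft_stat("repeated-measures ANOVA", statistic = f, df = df_use, p = p,
           effect_size = eta,
           effect_ci = partial_eta_sq_ci(f, df_use[1], df_use[2],
                                         level = eta_level),
           conf_level = eta_level, n = n,
           epsilon = eps, mauchly_w = W, mauchly_p = mauchly_p,
           gg_applied = gg_applied, df_uncorrected = c(df1, df2),
           ss_effect = ss_effect, ss_error = ss_error)
}
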