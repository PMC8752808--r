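#' Statistical layer: effect sizes, tests, intervals, power, normality
#'
#' Conventions used throughout the package: Cohen's d and confidence
#' intervals use the sample standard deviation (n - 1); significance of
#' per-pair statistics against a baseline uses a one-sided one-sample t test;
#' multiplicity over layers/areas is handled by Bonferroni correction.
#'
#' @name stats_layer
NULL

#' Cohen's d against a fixed baseline
#'
#' `(mean(values) - baseline) / sd(values)` with the sample SD (n - 1).
#'
#' @param values Numeric vector (n >= 2, non-constant).
#' @param baseline Baseline value (e.g. 50 for chance-level peak contrast).
#' @return Cohen's d.
#' @export
cohens_d <- function(values, baseline = 0) {
  assert_that(length(values) >= 2, "need n >= 2 values")
  s <- stats::sd(values)
  if (s == 0) stop_input("cohens_d undefined: zero standard deviation")
  (mean(values) - baseline) / s
}

#' One-sided one-sample t test (upper tail)
#'
#' p-value for the alternative `mean > mu0` from a Student t with n - 1
#' degrees of freedom. A zero-variance sample degenerates to p = 0 or 1 by
#' the sign of the mean shift (0.5 at equality), with a warning.
#'
#' @param values Numeric vector (n >= 2).
#' @param mu0 Null mean.
#' @return Upper-tail p-value.
#' @export
one_sided_t <- function(values, mu0 = 0) {
  assert_that(length(values) >= 2, "need n >= 2 values")
  n <- length(values)
  s <- stats::sd(values)
  if (s == 0) {
    warning("one_sided_t: zero variance; degenerate p-value")
    return(if (mean(values) > mu0) 0 else if (mean(values) < mu0) 1 else 0.5)
  }
  t <- (mean(values) - mu0) / (s / sqrt(n))
  stats::pt(t, df = n - 1, lower.tail = FALSE)
}

#' Bonferroni correction
#'
#' @param p Raw p-value(s).
#' @param m Number of comparisons (>= 1), e.g. the number of layers.
#' @return `min(1, m * p)` elementwise.
#' @export
bonferroni <- function(p, m) {
  assert_that(m >= 1, "`m` must be >= 1")
  pmin(1, m * p)
}

#' Pearson product-moment correlation
#'
#' @param x,y Aligned numeric vectors, n >= 3, both non-constant.
#' @return Pearson's r.
#' @export
pearson_r <- function(x, y) {
  assert_that(length(x) == length(y), "`x` and `y` must be aligned")
  assert_that(length(x) >= 3, "need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_input("pearson_r undefined for constant input")
  stats::cor(x, y)
}

#' Two-sided permutation test for a Pearson correlation
#'
#' Permutes the pairing of `y` against `x`. For n <= 7 the full `n!`
#' enumeration is used (an exact test); otherwise a seeded Monte-Carlo with
#' `n_perm` resamples and the add-one correction `(k + 1) / (n_perm + 1)`,
#' where `k` counts permutations with `|r| >= |r_observed|`.
#'
#' @param x,y Aligned numeric vectors.
#' @param n_perm Number of Monte-Carlo resamples (>= 999).
#' @param seed Integer seed making the Monte-Carlo p deterministic.
#' @return Two-sided p-value.
#' @export
mc_permutation_p <- function(x, y, n_perm = 1e5, seed = 1) {
  r_obs <- abs(pearson_r(x, y))
  n <- length(x)
  if (n <= 7) {
    perms <- permutations_all(n)
    rs <- apply(perms, 1, function(p) abs(stats::cor(x, y[p])))
    return(mean(rs >= r_obs - 1e-12))
  }
  assert_that(n_perm >= 999, "`n_perm` must be >= 999")
  k <- with_seed(seed, {
    sum(replicate(n_perm, abs(stats::cor(x, sample(y))) >= r_obs - 1e-12))
  })
  (k + 1) / (n_perm + 1)
}

# All permutations of 1..n as an (n!) x n matrix (n small).
permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(setdiff(seq_len(n), i)[sub], nrow(sub), n - 1))))
}

#' t-based 95% confidence interval of the mean
#'
#' `mean +/- t_{0.975, n-1} * SE`.
#'
#' @param values Numeric vector (n >= 2).
#' @return Length-2 vector `c(low, high)`.
#' @export
mean_ci95 <- function(values) {
  assert_that(length(values) >= 2, "need n >= 2 values")
  n <- length(values)
  se <- stats::sd(values) / sqrt(n)
  mean(values) + c(-1, 1) * stats::qt(0.975, n - 1) * se
}

#' Post-hoc power of a one-sided one-sample t test
#'
#' Power at effect size `d` and sample size `n` via the noncentral t
#' distribution with noncentrality `d * sqrt(n)`.
#'
#' @param d Cohen's d.
#' @param n Sample size (>= 2).
#' @param alpha Test level.
#' @return Power in `[0, 1]`.
#' @export
posthoc_power_t <- function(d, n, alpha = 0.01) {
  assert_that(n >= 2, "`n` must be >= 2")
  crit <- stats::qt(1 - alpha, df = n - 1)
  stats::pt(crit, df = n - 1, ncp = d * sqrt(n), lower.tail = FALSE)
}

#' Normality check with estimated parameters (Lilliefors-style)
#'
#' Kolmogorov-Smirnov statistic of the sample against a normal distribution
#' with mean and SD estimated from the sample itself; since that invalidates
#' the standard KS null, the p-value is obtained by a seeded Monte-Carlo over
#' normal samples of the same size with re-estimated parameters.
#'
#' @param values Numeric vector (n >= 5).
#' @param n_mc Monte-Carlo replicates.
#' @param seed Integer seed.
#' @return List with `statistic` (D) and `p`.
#' @export
ks_normality <- function(values, n_mc = 2000, seed = 1) {
  assert_that(length(values) >= 5, "need n >= 5 values")
  n <- length(values)
  ks_stat <- function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) return(1)
    z <- sort(pnorm(v, m, s))
    i <- seq_len(n)
    max(i / n - z, z - (i - 1) / n)
  }
  d_obs <- ks_stat(values)
  k <- with_seed(seed, sum(replicate(n_mc, ks_stat(rnorm(n)) >= d_obs - 1e-12)))
  list(statistic = d_obs, p = (k + 1) / (n_mc + 1))
}

#' Effect-size summary for a per-pair statistic against a baseline
#'
#' Bundles Cohen's d, the one-sided t p-value, and the 95% CI of the mean for
#' a vector of per-pair statistics, with an optional Bonferroni factor.
#'
#' @param values Per-pair statistics (typically 45 values).
#' @param baseline Null value (50 for peaks/accuracies in percent, 0 for
#'   amplitude differences).
#' @param correction Bonferroni factor applied to the reported `p_adj`
#'   (e.g. number of layers), or 1.
#' @return Object of class `effect_size_result` with fields `d`, `p`,
#'   `p_adj`, `ci95`, `mean`, `n`, `baseline`, `correction`.
#' @export
effect_size_result <- function(values, baseline = 0, correction = 1) {
  assert_that(length(values) >= 3, "need >= 3 pairs")
  d <- cohens_d(values, baseline)     # errors first on zero SD
  p <- one_sided_t(values, baseline)
  structure(
    list(d = d, p = p,
         p_adj = bonferroni(p, correction), ci95 = mean_ci95(values),
         mean = mean(values), n = length(values), baseline = baseline,
         correction = correction),
    class = "effect_size_result")
}

#' @export
print.effect_size_result <- function(x, ...) {
  cat(sprintf(
    "<effect_size_result> mean %.3f (baseline %g), d = %.3f, one-sided p = %.3g%s, 95%% CI [%.3f, %.3f], n = %d\n",
    x$mean, x$baseline, x$d, x$p,
    if (x$correction > 1) sprintf(" (adj %.3g, m = %d)", x$p_adj, x$correction) else "",
    x$ci95[1], x$ci95[2], x$n))
  invisible(x)
}
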