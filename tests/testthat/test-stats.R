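test_that("Cohen's d uses the sample SD and reflects about the baseline", {
  v <- c(60, 55, 50, 65, 45)
  expect_equal(cohens_d(v, 50), 5 / sd(v))
  expect_equal(cohens_d(v, 50), 0.632, tolerance = 1e-3)   # 5 / 7.9057
  expect_equal(cohens_d(100 - v, 50), -cohens_d(v, 50))
  expect_equal(cohens_d(c(-1, 0, 1), 0), 0)
  expect_error(cohens_d(rep(3, 4), 3), "zero standard deviation")
})

test_that("one-sided t matches the base t.test oracle and is monotone", {
  set.seed(1)
  x <- rnorm(12, mean = 0.4)
  expect_equal(one_sided_t(x, 0),
               t.test(x, mu = 0, alternative = "greater")$p.value,
               tolerance = 1e-12)
  # symmetric sample about mu0 gives exactly 0.5
  expect_equal(one_sided_t(c(-1, 0, 1), 0), 0.5)
  # n = 5, t = 2.132 sits at the classical 5% point
  x5 <- 2.132 / sqrt(5) + c(-1, -0.5, 0, 0.5, 1) / sd(c(-1, -0.5, 0, 0.5, 1))
  expect_equal(one_sided_t(x5, 0), 0.05, tolerance = 1e-3)
  # p decreases as the sample mean grows
  ps <- vapply(c(0, 0.5, 1), function(sh) one_sided_t(x + sh, 0), numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_warning(p0 <- one_sided_t(rep(1, 5), 0), "zero variance")
  expect_equal(p0, 0)
})

test_that("Bonferroni correction multiplies and caps at 1", {
  expect_equal(bonferroni(0.004, 19), 0.076)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(0.2, 10), 1)
})

test_that("pearson_r matches the covariance formula on a hand example", {
  x <- c(1, 2, 4, 7); y <- c(2, 1, 5, 6)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
})

test_that("permutation p is exact for small n and seeded for Monte-Carlo", {
  # independent exhaustive oracle (recursion written here, not the package's)
  enum_p <- function(x, y) {
    r0 <- abs(cor(x, y))
    k <- 0; tot <- 0
    rec <- function(rest, acc) {
      if (!length(rest)) {
        tot <<- tot + 1
        if (abs(cor(x, y[acc])) >= r0 - 1e-12) k <<- k + 1
        return(invisible())
      }
      for (i in seq_along(rest)) rec(rest[-i], c(acc, rest[i]))
    }
    rec(seq_along(y), integer(0))
    k / tot
  }
  set.seed(3)
  x <- rnorm(5); y <- rnorm(5)
  expect_equal(mc_permutation_p(x, y), enum_p(x, y))
  # perfectly correlated long vectors: only extreme permutations reach |r| = 1
  x20 <- rnorm(20)
  expect_equal(mc_permutation_p(x20, x20, n_perm = 999, seed = 2), 1 / 1000)
  xm <- rnorm(20); ym <- rnorm(20)
  expect_equal(mc_permutation_p(xm, ym, n_perm = 999, seed = 5),
               mc_permutation_p(xm, ym, n_perm = 999, seed = 5))
  # calibration: p is roughly uniform under independence
  set.seed(6)
  ps <- replicate(40, mc_permutation_p(rnorm(6), rnorm(6)))
  expect_lt(abs(mean(ps) - 0.5), 0.15)
})

test_that("95% CI matches t.test and hand arithmetic", {
  v <- c(1, 2, 3, 4)
  ci <- mean_ci95(v)
  expect_equal(ci, as.vector(t.test(v)$conf.int), tolerance = 1e-12)
  expect_equal(ci, 2.5 + c(-1, 1) * 3.182 * 0.6455, tolerance = 1e-3)
  expect_equal(mean_ci95(rep(2, 5)), c(2, 2))
  wide <- mean_ci95(v * 3)
  expect_gt(diff(wide), diff(ci))
})

test_that("post-hoc power matches a simulation oracle", {
  expect_equal(posthoc_power_t(0, 45, alpha = 0.01), 0.01, tolerance = 1e-10)
  expect_true(posthoc_power_t(0.8, 45, 0.01) > posthoc_power_t(0.4, 45, 0.01))
  expect_true(posthoc_power_t(0.5, 90, 0.01) > posthoc_power_t(0.5, 45, 0.01))
  # Monte-Carlo oracle at d = 0.5, n = 45, alpha = 0.01
  set.seed(11)
  m <- 20000; n <- 45
  X <- matrix(rnorm(m * n, mean = 0.5), n, m)
  tt <- colMeans(X) / (apply(X, 2, sd) / sqrt(n))
  mc <- mean(tt > qt(0.99, n - 1))
  expect_equal(posthoc_power_t(0.5, 45, 0.01), mc, tolerance = 0.01)
})

test_that("normality check agrees with the Lilliefors statistic and is seeded", {
  skip_if_not_installed("nortest")
  set.seed(12)
  v <- rnorm(50)
  r1 <- ks_normality(v, n_mc = 500, seed = 9)
  r2 <- ks_normality(v, n_mc = 500, seed = 9)
  expect_identical(r1, r2)
  # statistic equals the classical Lilliefors D
  expect_equal(r1$statistic, unname(nortest::lillie.test(v)$statistic),
               tolerance = 1e-10)
  expect_gt(r1$p, 0.05)
  skewed <- exp(rnorm(80, sd = 1.5))
  expect_lt(ks_normality(skewed, n_mc = 500, seed = 9)$p, 0.01)
})

test_that("one-sided t holds its nominal level under the null", {
  set.seed(13)
  m <- 4000; n <- 45
  X <- matrix(rnorm(m * n), n, m)
  ps <- apply(X, 2, function(v) one_sided_t(v, 0))
  rej <- mean(ps < 0.01)
  # binomial tolerance around the 1% nominal rate
  expect_lt(abs(rej - 0.01), 3 * sqrt(0.01 * 0.99 / m) + 0.002)
})

test_that("effect-size bundles are internally consistent", {
  v <- c(60, 55, 50, 65, 45)
  e <- effect_size_result(v, baseline = 50, correction = 5)
  expect_equal(e$d, cohens_d(v, 50))
  expect_equal(e$p, one_sided_t(v, 50))
  expect_equal(e$p_adj, bonferroni(e$p, 5))
  expect_equal(e$ci95, mean_ci95(v))
  expect_equal(e$n, 5L, ignore_attr = TRUE)
})
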