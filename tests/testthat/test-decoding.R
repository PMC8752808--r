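test_that("voxel selection ranks by |r| with stable tie-breaking", {
  set.seed(42)
  y <- 1:6
  z1 <- rnorm(6); z2 <- rnorm(6); z3 <- rnorm(6)
  X <- cbind(vector_with_cor(y, z1, 0.9),
             vector_with_cor(y, z2, 0.1),
             vector_with_cor(y, z3, -0.5))
  # brute-force oracle: order of |cor| computed directly
  oracle <- order(-abs(cor(X, y)))
  sel <- select_voxels(X, y, max_voxels = 2)
  expect_equal(as.integer(sel), oracle[1:2])
  expect_equal(as.integer(sel), c(1L, 3L))
  expect_false(attr(sel, "degenerate"))
  # cap at the voxel count
  expect_equal(as.integer(select_voxels(X, y, max_voxels = 10)), oracle)
  # selection is invariant to affine rescaling of the target
  expect_equal(as.integer(select_voxels(X, 3 * y - 7, max_voxels = 2)),
               as.integer(sel))
  # degenerate target
  d <- select_voxels(X, rep(2, 6), max_voxels = 2)
  expect_length(d, 0)
  expect_true(attr(d, "degenerate"))
})

test_that("decoder training matches closed-form OLS and interpolates noiseless data", {
  # 1-voxel toy: samples (x, y) = (0, 1), (1, 3) -> weight 2, intercept 1
  X1 <- matrix(c(0, 1), 2, 1)
  ds1 <- train_decoder_set(X1, list(layer1 = matrix(c(1, 3), 2, 2)),
                           max_voxels = 1)
  expect_equal(unname(ds1$layers$layer1$beta[, 1]), c(1, 2), tolerance = 1e-10)
  # noiseless y = Xw: exact interpolation when the support is selectable
  set.seed(1)
  X <- matrix(rnorm(40 * 6), 40, 6)
  w <- c(2, 0, -1, 0, 0, 0.5)
  Y <- cbind(X %*% w, X %*% rev(w))
  ds <- train_decoder_set(X, list(layer1 = Y), max_voxels = 6)
  pred <- decode_responses(ds, X)$layer1
  expect_equal(pred, Y, tolerance = 1e-8, ignore_attr = TRUE)
  # OLS oracle: brute-force normal equations on <= 8 voxels
  set.seed(2)
  Xs <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  ds2 <- train_decoder_set(Xs, list(layer1 = cbind(y, y)), max_voxels = 5)
  A <- cbind(1, Xs[, ds2$layers$layer1$selection[, 1]])
  beta_oracle <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(unname(ds2$layers$layer1$beta[, 1]), as.vector(beta_oracle),
               tolerance = 1e-8)
  # degenerate unit predicts its training mean
  ds3 <- train_decoder_set(Xs, list(layer1 = cbind(y, rep(3, 30))),
                           max_voxels = 5)
  expect_true(ds3$layers$layer1$degenerate[2])
  expect_equal(decode_responses(ds3, Xs)$layer1[, 2], rep(3, 30))
})

test_that("rank-deficient designs fall back to minimum-norm solutions", {
  set.seed(3)
  X <- matrix(rnorm(10 * 2), 10, 2)
  X4 <- cbind(X, X)                 # duplicated voxels: rank 2 of 4
  y <- X %*% c(1, -2)
  expect_message(
    ds <- train_decoder_set(X4, list(layer1 = cbind(y, y)), max_voxels = 4),
    "minimum-norm")
  expect_equal(decode_responses(ds, X4)$layer1[, 1], as.vector(y),
               tolerance = 1e-8)
})

test_that("decoding is an affine map of the response vector", {
  set.seed(4)
  X <- matrix(rnorm(30 * 8), 30, 8)
  Y <- list(layer1 = X %*% matrix(rnorm(8 * 3), 8, 3) + 1)
  ds <- train_decoder_set(X, Y, max_voxels = 8)
  # all-zero responses decode to the intercepts
  f0 <- decode_trial(ds, rep(0, 8))
  expect_equal(f0$layer1, unname(ds$layers$layer1$beta[1, ]))
  expect_identical(attr(f0, "provenance"), "decoded")
  x1 <- X[1, ]; x2 <- X[2, ]; a <- 0.3
  mix <- decode_trial(ds, a * x1 + (1 - a) * x2)
  f1 <- decode_trial(ds, x1); f2 <- decode_trial(ds, x2)
  expect_equal(mix$layer1, a * f1$layer1 + (1 - a) * f2$layer1,
               tolerance = 1e-10)
  expect_error(decode_trial(ds, rep(0, 5)), "voxel count")
})

test_that("z-normalization applies training stats and masks degenerate units", {
  st <- manual_stats(list(layer1 = c(2, 0, 1)), list(layer1 = c(0.5, 0, 2)))
  f <- lf(layer1 = c(3, 5, 1))
  z <- normalize_features(f, st)
  expect_equal(z$layer1[1], 2)                  # (3 - 2) / 0.5
  expect_true(is.na(z$layer1[2]))               # degenerate unit masked
  expect_equal(z$layer1[3], 0)
  # f = mu -> all zeros (non-degenerate units)
  z0 <- normalize_features(lf(layer1 = c(2, 0, 1)), st)
  expect_equal(z0$layer1[c(1, 3)], c(0, 0))
  # round trip through the inverse transform
  z2 <- normalize_features(lf(layer1 = c(2, 0, 1) + c(0.5, 0, 2) * c(1, 0, -2)), st)
  expect_equal(z2$layer1[c(1, 3)], c(1, -2))
  expect_error(normalize_features(lf(layer2 = 1:3), st), "cover")
})

test_that("pattern-correlation accuracy behaves at its fixed points", {
  set.seed(5)
  U <- 512
  truth <- list(layer1 = matrix(rnorm(U), 1))
  st <- manual_stats(list(layer1 = rep(0, U)), list(layer1 = rep(1, U)))
  expect_equal(unname(decoding_accuracy(truth, truth, st)[1, 1]), 1)
  neg <- list(layer1 = -truth$layer1)
  expect_equal(unname(decoding_accuracy(neg, truth, st)[1, 1]), -1)
  # an independently shuffled pattern decorrelates (null width ~ 1/sqrt(U))
  shuf <- list(layer1 = matrix(sample(truth$layer1), 1))
  expect_lt(abs(decoding_accuracy(shuf, truth, st)[1, 1]), 0.15)
})

test_that("variance matching rescales groups to their targets", {
  set.seed(6)
  v <- rnorm(40, mean = 3, sd = 2)
  f <- lf(layer1 = v)
  cur <- mean((v - mean(v))^2)
  # identity when the reference equals the current variance
  same <- variance_match(f, list(layer1 = cur))
  expect_equal(same$layer1, v, tolerance = 1e-12)
  # variance 4 -> target 1 scales deviations by 0.5 about the group mean
  v4 <- mean(v) + (v - mean(v)) * sqrt(4 / cur)
  half <- variance_match(lf(layer1 = v4), list(layer1 = 1))
  expect_equal(half$layer1 - mean(v4), (v4 - mean(v4)) * 0.5, tolerance = 1e-10)
  # postcondition: within-group variances equal the targets
  g <- rep(1:2, each = 20)
  out <- variance_match(f, list(layer1 = c(1.5, 0.25)), groups = list(layer1 = g))
  for (gi in 1:2) {
    vv <- out$layer1[g == gi]
    expect_equal(mean((vv - mean(vv))^2), c(1.5, 0.25)[gi], tolerance = 1e-8)
  }
  expect_warning(variance_match(lf(layer1 = rep(1, 5)), list(layer1 = 1)),
                 "unscaled")
})
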