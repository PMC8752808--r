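# Shared small scene for curve-level tests
local({
  bank <- tiny_bank(seed = 21)
  imgs <- generate_toy_images(6, size = 16, seed = 22)
  stats <- compute_feature_stats(bank, imgs[1:4])
  pair <- list(a = imgs[[5]], b = imgs[[6]])
  grid <- contrast_grid(5)

  test_that("a self-matched decoded pattern peaks at its generating contrast", {
    blend <- superimpose(pair$a, pair$b, 70)
    decoded <- extract_features(bank, blend)
    cv <- contrast_curve(decoded, pair, attended = "a", bank = bank,
                         stats = stats, grid = grid)
    expect_s3_class(cv, "contrast_curve")
    expect_true(all(cv$correlations >= -1 & cv$correlations <= 1))
    expect_equal(unname(peak_contrast(cv)), rep(70, 2))
    # orientation flip mirrors the curve on the weight axis
    cv_b <- contrast_curve(decoded, pair, attended = "b", bank = bank,
                           stats = stats, grid = grid)
    expect_equal(cv$correlations, cv_b$correlations[rev(seq_along(grid)), ],
                 tolerance = 1e-10)
    expect_equal(unname(peak_contrast(cv_b)), rep(30, 2))
  })

  test_that("identical pair members give a flat curve resolved to 50", {
    same <- list(a = imgs[[5]], b = imgs[[5]])
    decoded <- extract_features(bank, imgs[[5]])
    cv <- contrast_curve(decoded, same, attended = "a", bank = bank,
                         stats = stats, grid = grid)
    expect_lt(max(cv$correlations) - min(cv$correlations), 1e-10)
    expect_message(pk <- peak_contrast(cv, "layer1"), "flat")
    expect_equal(pk, 50)
  })

  test_that("pair-wise identification picks the better-correlated candidate", {
    fa <- extract_features(bank, pair$a)
    fb <- extract_features(bank, pair$b)
    expect_equal(unname(identify_pairwise(fa, fa, fb, stats)), rep("a", 2))
    expect_equal(unname(identify_pairwise(fb, fa, fb, stats)), rep("b", 2))
    expect_equal(unname(identify_pairwise(fa, fb, fb, stats)), rep("tie", 2))
    # 4-unit hand example with brute-force correlations as the oracle
    st4 <- manual_stats(list(layer1 = rep(0, 4)), list(layer1 = rep(1, 4)))
    d <- lf(layer1 = c(1, 0, 0, 0))
    a4 <- lf(layer1 = c(1, 0, 0, 0)); b4 <- lf(layer1 = c(0, 1, 0, 0))
    expect_equal(identify_pairwise(d, a4, b4, st4, layer = "layer1"), "a")
    expect_gt(cor(c(1, 0, 0, 0), c(1, 0, 0, 0)), cor(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  })
})

test_that("peak picking follows the argmax with the 50-closest tie rule", {
  g <- contrast_grid(5)
  mk <- function(r) structure(list(grid = g, correlations = matrix(r, ncol = 1,
                                   dimnames = list(NULL, "layer1")),
                                   attended = "a", pair = c("a", "b")),
                              class = "contrast_curve")
  expect_equal(peak_contrast(mk(seq(0, 1, length.out = 21)), "layer1"), 100)
  r <- rep(0, 21); r[g == 55] <- 1
  expect_equal(peak_contrast(mk(r), "layer1"), 55)
  r2 <- rep(0, 21); r2[g %in% c(40, 60)] <- 1
  expect_equal(peak_contrast(mk(r2), "layer1"), 40)   # equidistant -> lower
  r3 <- rep(0, 21); r3[g %in% c(35, 60)] <- 1
  expect_equal(peak_contrast(mk(r3), "layer1"), 60)   # closest to 50 wins
  # invariant under strictly increasing transforms of the correlations
  r4 <- runif(21)
  expect_equal(peak_contrast(mk(r4), "layer1"),
               peak_contrast(mk(tanh(3 * r4)), "layer1"))
})

test_that("peak summaries average valid trials per pair", {
  tp <- data.frame(pair = "p1", layer = "layer1",
                   peak = c(55, 60, 65, 60), valid = TRUE)
  s <- summarize_peaks(tp)
  expect_equal(s$mean_peak, 60)
  expect_equal(s$n_trials, 4)
  tp2 <- rbind(tp, data.frame(pair = "p1", layer = "layer1", peak = 100,
                              valid = FALSE))
  expect_equal(summarize_peaks(tp2)$mean_peak, 60)   # error trial excluded
  tp3 <- rbind(tp, data.frame(pair = "p2", layer = "layer1", peak = NA,
                              valid = TRUE))
  expect_message(s3 <- summarize_peaks(tp3), "p2")
  expect_equal(nrow(s3), 1)
})

test_that("peak shift effect reproduces hand arithmetic", {
  tab <- data.frame(pair = paste0("p", 1:5), layer = "layer1",
                    mean_peak = c(60, 55, 50, 65, 45), n_trials = 16)
  e <- peak_shift_effect(tab, "layer1")
  expect_equal(e$d, 5 / sd(c(60, 55, 50, 65, 45)))
  expect_equal(e$baseline, 50)
  tab0 <- transform(tab, mean_peak = 50 + c(-2, -1, 0, 1, 2))
  expect_equal(peak_shift_effect(tab0, "layer1")$d, 0)
})

test_that("identification tables turn scores into per-pair percent accuracies", {
  sc <- data.frame(pair = "p1", layer = "layer1",
                   score = c(1, 1, 1, 1, 1, 1, 0, 0), valid = TRUE)
  expect_equal(identification_table(sc)$accuracy, 75)
  sc2 <- data.frame(pair = rep(c("p1", "p2"), each = 4), layer = "layer1",
                    score = 1, valid = TRUE)
  expect_equal(identification_table(sc2)$accuracy, c(100, 100))
})

test_that("feature sets take the top fraction with index tie-breaking", {
  M10 <- matrix(rnorm(10), 1, dimnames = list("img1", NULL))
  s <- build_feature_sets(list(layer1 = M10), fraction = 0.10)
  expect_equal(s$layer1$img1, which.max(M10))
  v <- c(3, 1, 2, rep(0, 17))
  M20 <- matrix(v, 1, dimnames = list("img1", NULL))
  s2 <- build_feature_sets(list(layer1 = M20), fraction = 0.10)
  expect_equal(s2$layer1$img1, c(1L, 3L))       # ceil(2) units, ranked by value
  # identical decoded patterns give identical sets
  M2 <- rbind(img1 = v, img2 = v)
  s3 <- build_feature_sets(list(layer1 = M2), fraction = 0.10)
  expect_identical(s3$layer1$img1, s3$layer1$img2)
  expect_error(build_feature_sets(list(layer1 = M2), fraction = 0), "fraction")
})

test_that("amplitude profiles average the right unit sets", {
  st <- manual_stats(list(layer1 = rep(0, 4)), list(layer1 = rep(1, 4)))
  sets <- structure(list(layer1 = list(A = c(1L, 2L), B = c(2L, 3L),
                                       C = c(3L, 4L))),
                    class = "feature_set", fraction = 0.5)
  z <- amplitude_profile(lf(layer1 = rep(0, 4)), sets, st, "A", "B", "C")
  expect_equal(unlist(z[, c("amp_att", "amp_unatt", "amp_others")]),
               c(0, 0, 0), ignore_attr = TRUE)
  # overlapping sets hand example: decoded (2, 2, 0, 0), sets {1,2} and {2,3}
  p <- amplitude_profile(lf(layer1 = c(2, 2, 0, 0)), sets, st, "A", "B", "C")
  expect_equal(p$amp_att, 2)
  expect_equal(p$amp_unatt, 1)
  expect_equal(p$amp_others, 0)
  # disjoint support: +1 only on the attended set
  sets2 <- structure(list(layer1 = list(A = c(1L, 2L), B = c(3L, 4L))),
                     class = "feature_set", fraction = 0.5)
  p2 <- amplitude_profile(lf(layer1 = c(1, 1, 0, 0)), sets2, st, "A", "B")
  expect_equal(c(p2$amp_att, p2$amp_unatt), c(1, 0))
  expect_true(is.na(p2$amp_others))
  expect_error(amplitude_profile(lf(layer1 = rep(0, 4)), sets, st, "Z", "B", "C"),
               "empty feature set")
})

test_that("amplitude effects reproduce hand arithmetic and reject zero SD", {
  tab <- data.frame(pair = paste0("p", 1:5),
                    amp_att = c(2, 0, 1, 3, -1), amp_unatt = 0)
  e <- amplitude_effect(tab)
  expect_equal(e$d, 1 / sd(c(2, 0, 1, 3, -1)))
  expect_equal(e$d, 0.632, tolerance = 1e-3)
  bal <- data.frame(pair = paste0("p", 1:4),
                    amp_att = c(1, 2, 3, 4), amp_unatt = c(2, 1, 4, 3))
  expect_equal(amplitude_effect(bal)$d, 0)
  same <- data.frame(pair = paste0("p", 1:4), amp_att = 1, amp_unatt = 0)
  expect_error(amplitude_effect(same), "zero standard deviation")
})

test_that("rating aggregation pools conditions and cancels pure saliency", {
  rec <- data.frame(pair = rep(c("p1", "p2"), each = 20), correct = TRUE)
  agg <- aggregate_ratings(rec, "attended")
  expect_equal(agg$accuracy, c(100, 100))
  rec2 <- data.frame(pair = "p1", correct = rep(c(TRUE, FALSE), each = 10))
  expect_equal(aggregate_ratings(rec2, "single")$accuracy, 50)
  # a rater always choosing image A: right when A attended, wrong when B is
  rec3 <- data.frame(pair = "p1",
                     correct = rep(c(TRUE, FALSE), times = c(8, 8)))
  expect_equal(aggregate_ratings(rec3, "attended")$accuracy, 50)
})
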