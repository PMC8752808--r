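#' Synthetic encoding studies with a known attentional weight
#'
#' The simulator emulates the design of a feature-decoding attention study at
#' desk scale: a training session of passively viewed single images (default
#' 60 unique images x 2 repeats), and a test session of 10 single images x 16
#' trials plus all 45 image pairs x 2 attention conditions x 8 trials of
#' 50/50 superimposed images. Voxel responses arise from a sparse linear
#' readout of the feature bank's unit activations (z-scored by the study's
#' own training statistics) plus independent Gaussian noise; attention enters
#' through a ground-truth weight `alpha_true`: in `"contrast"` mode the
#' attention-trial response encodes the features of the
#' `superimpose(attended, unattended, 100 * alpha_true)` stimulus, in
#' `"gain"` mode the convex combination
#' `alpha_true * f(attended) + (1 - alpha_true) * f(unattended)` of the two
#' single-image feature vectors. `alpha_true = 0.5` is the null (no
#' modulation); recovering `100 * alpha_true` as the mean peak contrast
#' validates the whole pipeline.
#'
#' @name synthetic_data
NULL

pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Configure a synthetic study
#'
#' Defaults are the package's reference study conditions; `noise_sd` is the
#' per-voxel noise SD expressed as a multiple of that voxel's noiseless
#' training-response SD (0.5 = moderate noise).
#'
#' @param n_train_images,train_repeats Training session size (samples =
#'   product).
#' @param n_test_images Number of test images; pairs = all unordered
#'   combinations (45 for 10 images).
#' @param image_size,n_patterns Stimulus geometry and dictionary size for
#'   [generate_toy_images()].
#' @param trials_per_single,trials_per_condition Test-session trial counts.
#' @param area_names,voxels_per_area Simulated areas (layer tuning runs
#'   low-to-high along this order, emulating the V1 -> HVC gradient).
#' @param voxel_sparsity Feature units read by each voxel.
#' @param tuning_width SD (in layer index units) of each area's Gaussian
#'   layer-tuning profile; `area_tuning` may instead supply an explicit
#'   `n_areas x n_layers` weight matrix.
#' @param area_tuning Optional explicit tuning matrix (rows: areas).
#' @param noise_sd Noise SD as a multiple of each voxel's signal SD.
#' @param alpha_true Attended effective contrast in `[0.5, 1]`.
#' @param modulation_mode `"contrast"` or `"gain"`.
#' @param error_rate Probability a test trial is marked invalid (error
#'   trial); invalid trials are excluded by every aggregation.
#' @param max_voxels Per-unit voxel cap used when training decoders on this
#'   study (kept below the training sample count at the default scale).
#' @param grid_step Contrast-grid step for the peak analysis.
#' @param feature_set_fraction Top fraction defining image feature sets.
#' @param bank_spec Optional [feature_bank_spec()]; default derives one of
#'   the reference geometry from `seed`.
#' @param seed Master seed; every stochastic component derives its own
#'   stream from it.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_train_images = 60, n_test_images = 10,
                         image_size = 64, n_patterns = 20,
                         train_repeats = 2,
                         trials_per_single = 16, trials_per_condition = 8,
                         area_names = c("V1", "V2", "V3", "V4", "HVC"),
                         voxels_per_area = 200, voxel_sparsity = 12,
                         tuning_width = 0.75, area_tuning = NULL,
                         noise_sd = 0.5, alpha_true = 0.65,
                         modulation_mode = c("contrast", "gain"),
                         error_rate = 0,
                         max_voxels = 100, grid_step = 5,
                         feature_set_fraction = 0.10,
                         bank_spec = NULL, seed = 1) {
  modulation_mode <- match.arg(modulation_mode)
  assert_that(alpha_true >= 0.5 && alpha_true <= 1,
              "`alpha_true` must lie in [0.5, 1]")
  assert_that(n_train_images >= 2 && n_test_images >= 2,
              "image counts must be >= 2")
  assert_that(train_repeats >= 1 && trials_per_single >= 1 &&
                trials_per_condition >= 1, "trial counts must be >= 1")
  assert_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  assert_that(error_rate >= 0 && error_rate < 1, "`error_rate` must be in [0, 1)")
  if (is.null(bank_spec))
    bank_spec <- feature_bank_spec(image_size = image_size,
                                   seed = seed + 23L)
  structure(
    list(n_train_images = n_train_images, n_test_images = n_test_images,
         image_size = image_size, n_patterns = n_patterns,
         train_repeats = train_repeats,
         trials_per_single = trials_per_single,
         trials_per_condition = trials_per_condition,
         area_names = area_names, voxels_per_area = voxels_per_area,
         voxel_sparsity = voxel_sparsity, tuning_width = tuning_width,
         area_tuning = area_tuning, noise_sd = noise_sd,
         alpha_true = alpha_true, modulation_mode = modulation_mode,
         error_rate = error_rate, max_voxels = max_voxels,
         grid_step = grid_step,
         feature_set_fraction = feature_set_fraction,
         bank_spec = bank_spec, seed = as.integer(seed)),
    class = "study_config")
}

#' Build the sparse linear encoding model
#'
#' Each voxel of area `a` reads `voxel_sparsity` feature units sampled with
#' probability proportional to `a`'s layer-tuning weights (units within a
#' layer are equiprobable), with standard-normal readout weights. The model
#' is deterministic given the config seed.
#'
#' @param config A [study_config()].
#' @param bank The study's feature bank.
#' @return Object of class `encoding_model`: `weights`
#'   (`voxels x total_units`), `voxel_areas`, `layer_of_unit`.
#' @export
make_encoding_model <- function(config, bank) {
  n_layers <- bank$spec$n_layers
  units <- bank$spec$units_per_layer
  n_area <- length(config$area_names)
  tuning <- config$area_tuning
  if (is.null(tuning)) {
    centers <- seq(1, n_layers, length.out = n_area)
    tuning <- outer(centers, seq_len(n_layers),
                    function(a, l) exp(-(l - a)^2 / (2 * config$tuning_width^2)))
  }
  assert_that(nrow(tuning) == n_area && ncol(tuning) == n_layers,
              "`area_tuning` must be n_areas x n_layers")
  if (any(rowSums(tuning) == 0))
    stop_input("encoding model: all-zero tuning weights for an area")
  layer_of_unit <- rep(seq_len(n_layers), units)
  tot <- sum(units)
  V <- n_area * config$voxels_per_area
  with_seed(config$seed + 37L, {
    W <- matrix(0, V, tot)
    for (a in seq_len(n_area)) {
      p <- tuning[a, layer_of_unit] / units[layer_of_unit]
      p <- p / sum(p)
      for (v in seq_len(config$voxels_per_area)) {
        uu <- sample.int(tot, config$voxel_sparsity, prob = p)
        W[(a - 1) * config$voxels_per_area + v, uu] <- rnorm(config$voxel_sparsity)
      }
    }
    structure(
      list(weights = W,
           voxel_areas = rep(config$area_names, each = config$voxels_per_area),
           layer_of_unit = layer_of_unit),
      class = "encoding_model")
  })
}

# Noiseless voxel responses for per-layer feature matrices (samples x units),
# encoding z-scored (training-stats) features through the readout weights.
noiseless_responses <- function(model, features, stats) {
  Z <- do.call(cbind, normalize_features(features, stats))
  Z[!is.finite(Z)] <- 0
  Z %*% t(model$weights)
}

add_noise <- function(R0, sigma, seed) {
  if (all(sigma == 0)) return(R0)
  with_seed(seed, R0 + matrix(rnorm(length(R0)), nrow(R0)) %*% diag(sigma))
}

#' Simulate the training session
#'
#' One trial per (image, repeat); the response is the noiseless readout of
#' the image's features plus Gaussian noise with per-voxel SD
#' `noise_sd x` that voxel's noiseless training SD.
#'
#' @param model An [make_encoding_model()] result.
#' @param bank Feature bank.
#' @param images Named list of training images.
#' @param config The [study_config()].
#' @param stats Training [feature_stats] (over `images`).
#' @return List: `responses` ([response_matrix()]), `trial_table`,
#'   `features` (per-layer matrices aligned to trials), `noise_sigma`
#'   (per-voxel SDs, for reuse in the test session).
#' @export
simulate_training_session <- function(model, bank, images, config, stats) {
  F1 <- extract_feature_matrix(bank, images)
  reps <- config$train_repeats
  idx <- rep(seq_along(images), reps)
  Fr <- lapply(F1, function(m) m[idx, , drop = FALSE])
  R0 <- noiseless_responses(model, Fr, stats)
  sig0 <- apply(noiseless_responses(model, F1, stats), 2, stats::sd)
  sigma <- config$noise_sd * sig0
  R <- add_noise(R0, sigma, config$seed + 41L)
  tt <- data.frame(
    trial_id = sprintf("train%04d", seq_along(idx)),
    trial_type = "training",
    image_a = names(images)[idx], image_b = NA_character_,
    attended = NA_character_, valid = TRUE,
    response_ref = seq_along(idx), stringsAsFactors = FALSE)
  list(responses = response_matrix(R, model$voxel_areas), trial_table = tt,
       features = Fr, noise_sigma = sigma)
}

#' Simulate the test session
#'
#' Single-image trials (each test image repeated `trials_per_single` times)
#' and attention trials (every unordered pair, both attention conditions,
#' `trials_per_condition` trials each). The attention-trial stimulus encoding
#' follows `config$modulation_mode` and `config$alpha_true`.
#'
#' @inheritParams simulate_training_session
#' @param test_images Named list of test images.
#' @param noise_sigma Per-voxel noise SDs from the training session.
#' @return List: `responses`, `trial_table`, `features` (encoded feature
#'   matrices per trial), `pairs` (data frame of pair memberships).
#' @export
simulate_test_session <- function(model, bank, test_images, config, stats,
                                  noise_sigma) {
  ids <- names(test_images)
  alpha <- config$alpha_true
  Fsingle <- extract_feature_matrix(bank, test_images)   # per image
  cmb <- utils::combn(ids, 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                      pair = pair_id(cmb[1, ], cmb[2, ]),
                      stringsAsFactors = FALSE)
  # attention-trial encoded features, one row per (pair, condition)
  att_rows <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p)
    data.frame(pair = pairs$pair[p],
               attended = c(pairs$a[p], pairs$b[p]),
               unattended = c(pairs$b[p], pairs$a[p]),
               stringsAsFactors = FALSE)))
  if (config$modulation_mode == "contrast") {
    blends <- lapply(seq_len(nrow(att_rows)), function(i)
      superimpose(test_images[[att_rows$attended[i]]],
                  test_images[[att_rows$unattended[i]]], 100 * alpha))
    Fatt <- extract_feature_matrix(bank, blends)
  } else {
    ia <- match(att_rows$attended, ids)
    iu <- match(att_rows$unattended, ids)
    Fatt <- lapply(Fsingle, function(m)
      alpha * m[ia, , drop = FALSE] + (1 - alpha) * m[iu, , drop = FALSE])
  }
  ns <- config$trials_per_single
  na <- config$trials_per_condition
  sidx <- rep(seq_along(ids), each = ns)
  aidx <- rep(seq_len(nrow(att_rows)), each = na)
  Ftrial <- Map(function(ms, ma)
    rbind(ms[sidx, , drop = FALSE], ma[aidx, , drop = FALSE]),
    Fsingle, Fatt)
  R0 <- noiseless_responses(model, Ftrial, stats)
  R <- add_noise(R0, noise_sigma, config$seed + 43L)
  n_trials <- length(sidx) + length(aidx)
  valid <- if (config$error_rate > 0)
    with_seed(config$seed + 47L, stats::runif(n_trials) >= config$error_rate)
  else rep(TRUE, n_trials)
  tt <- rbind(
    data.frame(trial_id = sprintf("single%04d", seq_along(sidx)),
               trial_type = "single",
               image_a = ids[sidx], image_b = NA_character_,
               attended = NA_character_, stringsAsFactors = FALSE),
    data.frame(trial_id = sprintf("attn%04d", seq_along(aidx)),
               trial_type = "attention",
               image_a = att_rows$attended[aidx],
               image_b = att_rows$unattended[aidx],
               attended = att_rows$attended[aidx], stringsAsFactors = FALSE))
  tt$valid <- valid
  tt$response_ref <- seq_len(n_trials)
  list(responses = response_matrix(R, model$voxel_areas), trial_table = tt,
       features = Ftrial, pairs = pairs)
}

#' Simulate a complete study
#'
#' Generates the image set (training and test images share one dictionary so
#' that all stimuli live in the same low-dimensional family), the feature
#' bank, the encoding model, and both sessions; bundles the ground truth.
#'
#' @param config A [study_config()].
#' @return Object of class `synthetic_study`.
#' @export
simulate_study <- function(config) {
  n_img <- config$n_train_images + config$n_test_images
  imgs <- generate_toy_images(n_img, size = config$image_size,
                              seed = config$seed + 11L,
                              n_patterns = config$n_patterns)
  names(imgs) <- c(sprintf("train%03d", seq_len(config$n_train_images)),
                   sprintf("img%02d", seq_len(config$n_test_images)))
  train_images <- imgs[seq_len(config$n_train_images)]
  test_images <- imgs[config$n_train_images + seq_len(config$n_test_images)]
  bank <- build_feature_bank(config$bank_spec)
  stats <- compute_feature_stats(bank, train_images)
  model <- make_encoding_model(config, bank)
  training <- simulate_training_session(model, bank, train_images, config, stats)
  test <- simulate_test_session(model, bank, test_images, config, stats,
                                training$noise_sigma)
  structure(
    list(config = config, bank = bank, stats = stats, model = model,
         train_images = train_images, test_images = test_images,
         training = training, test = test,
         ground_truth = list(alpha_true = config$alpha_true,
                             modulation_mode = config$modulation_mode,
                             seed = config$seed)),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>",
      length(x$train_images), "train x", x$config$train_repeats, "reps;",
      length(x$test_images), "test images,",
      nrow(x$test$pairs), "pairs;",
      sprintf("alpha_true = %.2f (%s mode), noise_sd = %.2f, seed %d\n",
              x$config$alpha_true, x$config$modulation_mode,
              x$config$noise_sd, x$config$seed))
  invisible(x)
}
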