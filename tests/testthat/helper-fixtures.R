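# Small fixtures shared across test files; everything is generated in code.

tiny_bank_spec <- function(seed = 7) {
  feature_bank_spec(n_layers = 2, units_per_layer = c(8, 4),
                    image_size = 16, filter_size = 4, seed = seed)
}

tiny_bank <- function(seed = 7) build_feature_bank(tiny_bank_spec(seed))

# A reduced-scale study configuration for fast unit tests (not the reference
# study conditions; those are study_config() defaults).
tiny_config <- function(seed = 7, ...) {
  args <- list(n_train_images = 12, n_test_images = 4, image_size = 16,
               n_patterns = 6, train_repeats = 2, trials_per_single = 3,
               trials_per_condition = 2, voxels_per_area = 12,
               voxel_sparsity = 3, max_voxels = 10,
               bank_spec = feature_bank_spec(
                 n_layers = 3, units_per_layer = c(24, 12, 6),
                 image_size = 16, filter_size = 4, seed = seed + 23L),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(study_config, args)
}

# Deterministic feature_stats for hand-built unit vectors.
manual_stats <- function(mean_list, sd_list) {
  structure(list(
    mean = mean_list, sd = sd_list,
    degenerate = lapply(sd_list, function(s) s == 0),
    n_images = NA, layers = names(mean_list)),
    class = "feature_stats")
}

# layer_features from plain vectors
lf <- function(..., provenance = "decoded") {
  structure(list(...), class = "layer_features", provenance = provenance)
}

# Build x with an exact target correlation r against standardized y,
# using an orthogonal helper direction z.
vector_with_cor <- function(y, z, r) {
  ys <- (y - mean(y)) / sd(y)
  zr <- residuals(lm(z ~ ys))
  zs <- zr / sd(zr)
  r * ys + sqrt(1 - r^2) * zs
}
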