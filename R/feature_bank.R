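#' Deterministic hierarchical feature bank
#'
#' A fixed (never trained) stack of linear filter layers standing in for a
#' large pretrained image network at desk scale. Layer 1 consists of localized
#' signed random filters with a positive mean, so that typical stimuli drive
#' units in their linear regime; deeper layers are dense zero-mean random
#' projections. Half-wave rectification is applied *between* layers only: the
#' exposed output of every layer is its pre-rectification value, and layer 1
#' is therefore an exactly linear, bias-free function of the image.
#'
#' @name feature_bank
NULL

#' Specify a feature bank
#'
#' @param n_layers Number of layers (>= 2).
#' @param units_per_layer Integer vector of unit counts, one per layer
#'   (all >= 2; a monotone non-increasing profile mimics a visual hierarchy).
#' @param image_size Input image side length in pixels.
#' @param filter_size Side length of the localized layer-1 filters.
#' @param seed Integer seed; fixes the filter tensors bit-for-bit.
#' @return An object of class `feature_bank_spec`.
#' @export
feature_bank_spec <- function(n_layers = 5,
                              units_per_layer = c(512, 256, 128, 64, 32),
                              image_size = 64,
                              filter_size = 8,
                              seed = 1) {
  assert_that(n_layers >= 2, "`n_layers` must be >= 2")
  assert_that(length(units_per_layer) == n_layers,
              "`units_per_layer` must have one entry per layer")
  assert_that(all(units_per_layer >= 2), "all unit counts must be >= 2")
  assert_that(filter_size >= 2 && filter_size <= image_size,
              "`filter_size` must be in [2, image_size]")
  structure(
    list(n_layers = as.integer(n_layers),
         units_per_layer = as.integer(units_per_layer),
         image_size = as.integer(image_size),
         filter_size = as.integer(filter_size),
         seed = as.integer(seed)),
    class = "feature_bank_spec")
}

#' Build a feature bank from its specification
#'
#' Filters are drawn once from the spec's seed and never trained. Layer-1
#' rows are localized `filter_size x filter_size x 3` patches with weights
#' `N(0.15, 1)`; the positive mean keeps typical in-range stimuli above the
#' rectification threshold of the next layer. Layers `l >= 2` are dense
#' `N(0, 1/sqrt(fan_in))` maps. No biases anywhere.
#'
#' @param spec A [feature_bank_spec()].
#' @return An object of class `feature_bank` with elements `spec`,
#'   `filters` (list of weight matrices) and `layer_names`.
#' @export
build_feature_bank <- function(spec) {
  if (!inherits(spec, "feature_bank_spec"))
    stop_input("`spec` must be a feature_bank_spec")
  S <- spec$image_size
  fs <- spec$filter_size
  npix <- S * S * 3
  units <- spec$units_per_layer
  filters <- with_seed(spec$seed, {
    W1 <- matrix(0, units[1], npix)
    for (u in seq_len(units[1])) {
      px <- sample.int(S - fs + 1, 1)
      py <- sample.int(S - fs + 1, 1)
      for (c in 1:3) {
        idx <- as.vector(outer(px:(px + fs - 1), (py:(py + fs - 1) - 1) * S, "+")) +
          (c - 1) * S * S
        W1[u, idx] <- rnorm(fs * fs, mean = 0.15, sd = 1)
      }
    }
    out <- vector("list", spec$n_layers)
    out[[1]] <- W1
    for (l in seq_len(spec$n_layers)[-1])
      out[[l]] <- matrix(rnorm(units[l] * units[l - 1], 0, 1 / sqrt(units[l - 1])),
                         units[l], units[l - 1])
    out
  })
  structure(
    list(spec = spec, filters = filters,
         layer_names = paste0("layer", seq_len(spec$n_layers))),
    class = "feature_bank")
}

#' @export
print.feature_bank <- function(x, ...) {
  cat("<feature_bank>", x$spec$n_layers, "layers,",
      paste(x$spec$units_per_layer, collapse = "/"), "units,",
      sprintf("%dx%dx3 input, seed %d\n", x$spec$image_size, x$spec$image_size,
              x$spec$seed))
  invisible(x)
}

new_layer_features <- function(values, provenance = "stimulus") {
  structure(values, class = "layer_features", provenance = provenance)
}

#' @export
print.layer_features <- function(x, ...) {
  cat("<layer_features>", attr(x, "provenance"), "|",
      paste(sprintf("%s:%d", names(x), lengths(x)), collapse = " "), "\n")
  invisible(x)
}

# images -> npix x n matrix, with bilinear resizing to the bank geometry
images_to_matrix <- function(bank, images) {
  S <- bank$spec$image_size
  vapply(images, function(img) {
    validate_image(img)
    if (any(img < 0) || any(img > 1))
      stop_input("image values must lie in [0, 1]")
    as.vector(resize_image(img, S))
  }, numeric(S * S * 3))
}

#' Extract hierarchical features from one image
#'
#' Images are resized (bilinearly) to the bank's input geometry if needed.
#' Returned values are pre-rectification layer outputs.
#'
#' @param bank A [build_feature_bank()] result.
#' @param image A `height x width x 3` array with values in `[0, 1]`.
#' @return A `layer_features` object: a named list, one numeric vector per
#'   layer, with provenance `"stimulus"`.
#' @export
extract_features <- function(bank, image) {
  M <- extract_feature_matrix(bank, list(image))
  new_layer_features(lapply(M, function(m) m[1, ]), provenance = "stimulus")
}

#' Extract features for many images at once
#'
#' @param bank A feature bank.
#' @param images List of images.
#' @return Named list with one `n_images x n_units` matrix per layer
#'   (pre-rectification values).
#' @export
extract_feature_matrix <- function(bank, images) {
  X <- images_to_matrix(bank, images)          # npix x n
  out <- vector("list", bank$spec$n_layers)
  names(out) <- bank$layer_names
  f <- bank$filters[[1]] %*% X
  out[[1]] <- t(f)
  for (l in seq_len(bank$spec$n_layers)[-1]) {
    f <- bank$filters[[l]] %*% pmax(f, 0)      # rectify between layers only
    out[[l]] <- t(f)
  }
  out
}

#' Per-unit feature statistics over a training image set
#'
#' Means and standard deviations of every feature unit over the supplied
#' images, used downstream for z-score normalization of stimulus-computed and
#' decoded features alike. The population convention (divide by n) is used
#' for the standard deviation. Units with zero variance are flagged
#' degenerate and masked out of all downstream correlations.
#'
#' @param bank A feature bank.
#' @param images List of at least 2 images.
#' @return An object of class `feature_stats`: per layer, `mean`, `sd`
#'   (population), logical `degenerate`, plus `n_images`.
#' @export
compute_feature_stats <- function(bank, images) {
  assert_that(length(images) >= 2, "need at least 2 images for feature stats")
  F <- extract_feature_matrix(bank, images)
  feature_stats_from_matrix(F, n_images = length(images))
}

# Stats directly from per-layer feature matrices (n x units).
feature_stats_from_matrix <- function(F, n_images = nrow(F[[1]])) {
  structure(
    list(mean = lapply(F, colMeans),
         sd = lapply(F, col_sd_pop),
         degenerate = lapply(F, function(m) col_sd_pop(m) == 0),
         n_images = n_images,
         layers = names(F)),
    class = "feature_stats")
}

#' @export
print.feature_stats <- function(x, ...) {
  cat("<feature_stats>", length(x$layers), "layers over", x$n_images, "images;",
      sum(vapply(x$degenerate, sum, 0L)), "degenerate units\n")
  invisible(x)
}
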