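#' File formats and run configuration
#'
#' Plain-text interchange: trial tables, per-pair results and effect-size
#' summaries as TSV; feature matrices, responses and decoder weights as an
#' *array container* — a directory of TSV matrices with a JSON sidecar naming
#' the arrays and their dimensions; images as 8-bit RGB PNG mapped to
#' `[0, 1]`; run configuration as YAML with strict key checking.
#'
#' @name pipeline_io
NULL

run_config_defaults <- function() {
  list(
    study = list(
      n_train_images = 60, n_test_images = 10, image_size = 64,
      n_patterns = 20, train_repeats = 2, trials_per_single = 16,
      trials_per_condition = 8, voxels_per_area = 200, voxel_sparsity = 12,
      tuning_width = 0.75, noise_sd = 0.5, alpha_true = 0.65,
      modulation_mode = "contrast", error_rate = 0),
    decoding = list(max_voxels = 100, area = "VC"),
    analysis = list(grid_step = 5, feature_set_fraction = 0.10),
    stats = list(alpha = 0.01, n_perm = 100000),
    seed = 1)
}

merge_checked <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_input(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]])) {
      if (!is.list(user[[key]]))
        stop_input(sprintf("configuration key '%s' must be a section", full))
      defaults[[key]] <- merge_checked(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Parse a run configuration file
#'
#' Reads a YAML configuration, fills defaults, rejects unknown keys with an
#' error naming the key, validates values, and stamps the result with an
#' FNV-1a hash for provenance. An empty (or missing-section) file yields all
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Object of class `run_config` (nested list with attribute
#'   `config_hash`).
#' @export
parse_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    assert_that(file.exists(path), sprintf("config file '%s' not found", path))
    user <- yaml::read_yaml(path) %||% list()
  }
  cfg <- merge_checked(run_config_defaults(), user)
  assert_that(cfg$decoding$max_voxels >= 1, "decoding.max_voxels must be >= 1")
  assert_that(cfg$study$alpha_true >= 0.5 && cfg$study$alpha_true <= 1,
              "study.alpha_true must lie in [0.5, 1]")
  assert_that(cfg$analysis$grid_step > 0 && 100 %% cfg$analysis$grid_step == 0,
              "analysis.grid_step must divide 100")
  assert_that(cfg$stats$alpha > 0 && cfg$stats$alpha < 1,
              "stats.alpha must lie in (0, 1)")
  attr(cfg, "config_hash") <- fnv1a_hash(deparse(cfg))
  class(cfg) <- "run_config"
  cfg
}

# run_config -> study_config (flat constructor arguments)
config_to_study <- function(cfg, seed = NULL) {
  s <- cfg$study
  study_config(
    n_train_images = s$n_train_images, n_test_images = s$n_test_images,
    image_size = s$image_size, n_patterns = s$n_patterns,
    train_repeats = s$train_repeats, trials_per_single = s$trials_per_single,
    trials_per_condition = s$trials_per_condition,
    voxels_per_area = s$voxels_per_area, voxel_sparsity = s$voxel_sparsity,
    tuning_width = s$tuning_width, noise_sd = s$noise_sd,
    alpha_true = s$alpha_true, modulation_mode = s$modulation_mode,
    error_rate = s$error_rate, max_voxels = cfg$decoding$max_voxels,
    grid_step = cfg$analysis$grid_step,
    feature_set_fraction = cfg$analysis$feature_set_fraction,
    seed = seed %||% cfg$seed)
}

trial_table_columns <- c("trial_id", "trial_type", "image_a", "image_b",
                         "attended", "valid", "response_ref")

#' Read / write trial tables
#'
#' TSV with columns `trial_id, trial_type, image_a, image_b, attended,
#' valid, response_ref`; the round trip is lossless. Reading validates the
#' schema and reports the first offending row: `attended` must be one of the
#' pair members on attention trials, and `valid` must parse as a boolean.
#'
#' @param table A trial-table data frame.
#' @param path File path.
#' @return `read_trial_table()`: the validated data frame.
#' @export
write_trial_table <- function(table, path) {
  assert_that(all(trial_table_columns %in% names(table)),
              "trial table is missing required columns")
  utils::write.table(table[, trial_table_columns], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "NA")
  missing <- setdiff(trial_table_columns, names(tt))
  if (length(missing))
    stop_input(sprintf("trial table missing column(s): %s",
                       paste(missing, collapse = ", ")))
  if (!is.logical(tt$valid)) {
    v <- toupper(as.character(tt$valid))
    bad <- which(!v %in% c("TRUE", "FALSE", "T", "F"))
    if (length(bad))
      stop_input(sprintf("row %d: 'valid' is not a boolean", bad[1]))
    tt$valid <- v %in% c("TRUE", "T")
  }
  att <- which(tt$trial_type == "attention")
  bad <- att[!(tt$attended[att] == tt$image_a[att] |
                 tt$attended[att] == tt$image_b[att])]
  if (length(bad))
    stop_input(sprintf("row %d: attended image is not a member of the pair",
                       bad[1]))
  tt
}

#' Read / write an array container
#'
#' A directory holding one TSV per named matrix plus a `sidecar.json`
#' recording names, dimensions and optional metadata. Used for feature
#' matrices, responses, statistics and decoder weights.
#'
#' @param arrays Named list of numeric matrices (or vectors).
#' @param dir Container directory (created if needed).
#' @param meta Optional metadata list stored in the sidecar.
#' @return `read_array_container()`: list with elements `arrays`, `meta`.
#' @export
write_array_container <- function(arrays, dir, meta = list()) {
  assert_that(length(names(arrays)) == length(arrays) && all(nzchar(names(arrays))),
              "`arrays` must be a fully named list")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list(arrays = list(), meta = meta)
  for (nm in names(arrays)) {
    m <- as.matrix(arrays[[nm]])
    utils::write.table(m, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    sidecar$arrays[[nm]] <- list(dims = dim(m))
  }
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_array_container
#' @export
read_array_container <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  assert_that(file.exists(sc_path),
              sprintf("no sidecar.json in '%s'", dir))
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  arrays <- lapply(names(sc$arrays), function(nm) {
    m <- as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                     sep = "\t", header = FALSE))
    dimnames(m) <- NULL
    m
  })
  names(arrays) <- names(sc$arrays)
  list(arrays = arrays, meta = sc$meta)
}

#' Read / write images as PNG
#'
#' 8-bit RGB PNG with intensities mapped to `[0, 1]`.
#'
#' @param img A `height x width x 3` array in `[0, 1]`.
#' @param path File path.
#' @return `read_image_png()`: the image array.
#' @export
write_image_png <- function(img, path) {
  validate_image(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE][, , 1:3]
}

# --- decoder-set container -------------------------------------------------

write_decoder_set <- function(decoders, dir) {
  arrays <- list()
  for (l in names(decoders$layers)) {
    L <- decoders$layers[[l]]
    arrays[[paste0(l, "_selection")]] <- L$selection
    arrays[[paste0(l, "_beta")]] <- L$beta
    arrays[[paste0(l, "_degenerate")]] <- matrix(as.numeric(L$degenerate), 1)
    arrays[[paste0(l, "_stat_mean")]] <- matrix(decoders$stats$mean[[l]], 1)
    arrays[[paste0(l, "_stat_sd")]] <- matrix(decoders$stats$sd[[l]], 1)
  }
  meta <- list(area = decoders$area, max_voxels = decoders$max_voxels,
               n_train = decoders$n_train,
               voxel_columns = decoders$voxel_columns,
               layers = names(decoders$layers),
               n_images = decoders$stats$n_images)
  write_array_container(arrays, dir, meta = meta)
}

read_decoder_set <- function(dir) {
  ct <- read_array_container(dir)
  layer_names <- unlist(ct$meta$layers)
  layers <- lapply(layer_names, function(l) {
    list(selection = ct$arrays[[paste0(l, "_selection")]],
         beta = ct$arrays[[paste0(l, "_beta")]],
         degenerate = as.logical(ct$arrays[[paste0(l, "_degenerate")]][1, ]))
  })
  names(layers) <- layer_names
  means <- lapply(layer_names, function(l) ct$arrays[[paste0(l, "_stat_mean")]][1, ])
  sds <- lapply(layer_names, function(l) ct$arrays[[paste0(l, "_stat_sd")]][1, ])
  names(means) <- names(sds) <- layer_names
  stats <- structure(
    list(mean = means, sd = sds,
         degenerate = lapply(sds, function(s) s == 0),
         n_images = ct$meta$n_images, layers = layer_names),
    class = "feature_stats")
  structure(
    list(area = ct$meta$area, voxel_columns = unlist(ct$meta$voxel_columns),
         max_voxels = ct$meta$max_voxels, n_train = ct$meta$n_train,
         layers = layers, stats = stats),
    class = "decoder_set")
}
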