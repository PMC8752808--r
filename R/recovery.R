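#' Analyze decoded test-session features
#'
#' The full modulation analysis on an already-decoded test session: per-trial
#' peak contrasts with per-pair summaries and per-layer effect sizes,
#' attended-image (and optionally single-image) pair-wise identification, and
#' feature-set amplitude modulation. Used both by
#' [run_recovery_experiment()] and by the command-line `analyze` stage.
#'
#' @param decoded Named list of raw decoded feature matrices
#'   (`test trials x units` per layer), aligned with `trial_table` rows.
#' @param trial_table Test-session trial table (see [read_trial_table()]).
#' @param test_images Named list of the test images.
#' @param bank,stats Feature bank and training [feature_stats].
#' @param grid_step Contrast-grid step in percent.
#' @param feature_set_fraction Top fraction defining image feature sets.
#' @param single_identification Also run single-image identification?
#' @return List with `decoding_accuracy`, `trial_peaks`, `peak_summary`,
#'   `peak_effects`, `mean_peak`, `identification`, `single_identification`,
#'   `amplitude`, `feature_sets`.
#' @export
analyze_decoded <- function(decoded, trial_table, test_images, bank, stats,
                            grid_step = 5, feature_set_fraction = 0.10,
                            single_identification = TRUE) {
  layers <- names(decoded)
  n_layers <- length(layers)
  grid <- contrast_grid(grid_step)
  tt <- trial_table
  Dz <- normalize_features(decoded, stats)
  keep <- lapply(layers, function(l) which(!stats$degenerate[[l]]))
  names(keep) <- layers
  ids <- names(test_images)

  ## --- decoding accuracy on valid single-image trials
  srows <- which(tt$trial_type == "single" & tt$valid)
  simg <- match(tt$image_a[srows], ids)
  Fsingle <- extract_feature_matrix(bank, test_images)
  Sz <- normalize_features(Fsingle, stats)
  acc <- vapply(layers, function(l) {
    k <- keep[[l]]
    mean(vapply(seq_along(srows), function(i)
      stats::cor(Dz[[l]][srows[i], k], Sz[[l]][simg[i], k]), numeric(1)))
  }, numeric(1))

  ## --- per-pair candidate features, contrast curves and identification
  cmb <- utils::combn(ids, 2)
  pairs <- data.frame(a = cmb[1, ], b = cmb[2, ],
                      pair = pair_id(cmb[1, ], cmb[2, ]),
                      stringsAsFactors = FALSE)
  arow <- which(tt$trial_type == "attention")
  trial_peaks <- id_scores <- vector("list", nrow(pairs) * 2 * n_layers)
  ci <- 0
  g_n <- length(grid)
  for (p in seq_len(nrow(pairs))) {
    cand <- candidate_features(bank, test_images[[pairs$a[p]]],
                               test_images[[pairs$b[p]]], grid, stats)
    for (att in c(pairs$a[p], pairs$b[p])) {
      rows <- arow[tt$image_a[arow] == att &
                     pair_id(tt$image_a[arow], tt$image_b[arow]) == pairs$pair[p]]
      if (!length(rows)) next
      orient <- if (att == pairs$a[p]) seq_len(g_n) else rev(seq_len(g_n))
      for (l in layers) {
        k <- keep[[l]]
        Cc <- stats::cor(t(Dz[[l]][rows, k, drop = FALSE]),
                         t(cand[[l]][orient, k, drop = FALSE]))
        pk <- apply(Cc, 1, function(r) {
          cnd <- which(r == max(r)); w <- grid[cnd]
          w[order(abs(w - 50), w)][1]
        })
        ci <- ci + 1
        trial_peaks[[ci]] <- data.frame(
          pair = pairs$pair[p], layer = l, trial_id = tt$trial_id[rows],
          peak = pk, valid = tt$valid[rows], stringsAsFactors = FALSE)
        # identification against the pure candidates on the oriented axis:
        # attended = w 100, unattended = w 0
        ra <- Cc[, g_n]; rb <- Cc[, 1]
        id_scores[[ci]] <- data.frame(
          pair = pairs$pair[p], layer = l,
          score = ifelse(ra > rb, 1, ifelse(rb > ra, 0, 0.5)),
          valid = tt$valid[rows], stringsAsFactors = FALSE)
      }
    }
  }
  trial_peaks <- do.call(rbind, trial_peaks[seq_len(ci)])
  id_scores <- do.call(rbind, id_scores[seq_len(ci)])

  # a zero across-pair SD (e.g. exact noiseless recovery) makes the effect
  # size undefined; report NULL for that layer instead of failing the run
  try_effect <- function(expr) tryCatch(suppressWarnings(expr),
                                        error = function(e) NULL)
  peak_summary <- summarize_peaks(trial_peaks)
  peak_effects <- lapply(layers, function(l)
    try_effect(peak_shift_effect(peak_summary, l, correction = n_layers)))
  names(peak_effects) <- layers
  mean_peak <- vapply(layers, function(l)
    mean(peak_summary$mean_peak[peak_summary$layer == l]), numeric(1))

  id_table <- identification_table(id_scores)
  id_effects <- lapply(layers, function(l)
    try_effect(identification_effect(id_table, l, correction = n_layers)))
  names(id_effects) <- layers
  id_mean <- vapply(layers, function(l)
    mean(id_table$accuracy[id_table$layer == l]), numeric(1))

  ## --- single-image identification (nine false candidates per trial)
  single_id <- NULL
  if (single_identification) {
    sc <- vector("list", n_layers)
    for (li in seq_along(layers)) {
      l <- layers[li]; k <- keep[[l]]
      Cc <- stats::cor(t(Dz[[l]][srows, k, drop = FALSE]),
                       t(Sz[[l]][, k, drop = FALSE]))
      rows <- lapply(seq_along(srows), function(i) {
        true <- simg[i]; false <- setdiff(seq_along(ids), true)
        rt <- Cc[i, true]; rf <- Cc[i, false]
        data.frame(pair = pair_id(ids[true], ids[false]), layer = l,
                   score = ifelse(rt > rf, 1, ifelse(rf > rt, 0, 0.5)),
                   valid = TRUE, stringsAsFactors = FALSE)
      })
      sc[[li]] <- do.call(rbind, rows)
    }
    single_table <- identification_table(do.call(rbind, sc))
    single_effects <- lapply(layers, function(l)
      try_effect(identification_effect(single_table, l, correction = n_layers)))
    names(single_effects) <- layers
    single_id <- list(table = single_table, effects = single_effects,
                      mean_accuracy = vapply(layers, function(l)
                        mean(single_table$accuracy[single_table$layer == l]),
                        numeric(1)))
  }

  ## --- feature sets and amplitude modulation
  mean_dec <- lapply(layers, function(l) {
    M <- do.call(rbind, lapply(seq_along(ids), function(i)
      colMeans(Dz[[l]][srows[simg == i], , drop = FALSE])))
    rownames(M) <- ids
    M
  })
  names(mean_dec) <- layers
  sets <- build_feature_sets(mean_dec, fraction = feature_set_fraction)
  amp_rows <- vector("list", n_layers)
  for (li in seq_along(layers)) {
    l <- layers[li]
    SM <- vapply(ids, function(id)
      rowMeans(Dz[[l]][arow, sets[[l]][[id]], drop = FALSE], na.rm = TRUE),
      numeric(length(arow)))
    ia <- match(tt$image_a[arow], ids)
    iu <- match(tt$image_b[arow], ids)
    aa <- SM[cbind(seq_along(arow), ia)]
    au <- SM[cbind(seq_along(arow), iu)]
    ao <- (rowSums(SM) - aa - au) / (length(ids) - 2)
    amp_rows[[li]] <- data.frame(
      pair = pair_id(tt$image_a[arow], tt$image_b[arow]), layer = l,
      amp_att = aa, amp_unatt = au, amp_others = ao,
      valid = tt$valid[arow], stringsAsFactors = FALSE)
  }
  amp_trials <- do.call(rbind, amp_rows)
  av <- amp_trials[amp_trials$valid, ]
  amp_pair <- stats::aggregate(cbind(amp_att, amp_unatt, amp_others) ~ pair + layer,
                               data = av, FUN = mean)
  amp_effects <- lapply(layers, function(l)
    try_effect(amplitude_effect(amp_pair[amp_pair$layer == l, ],
                                correction = n_layers)))
  names(amp_effects) <- layers

  list(decoding_accuracy = acc,
       trial_peaks = trial_peaks,
       peak_summary = peak_summary, peak_effects = peak_effects,
       mean_peak = mean_peak,
       identification = list(table = id_table, effects = id_effects,
                             mean_accuracy = id_mean),
       single_identification = single_id,
       amplitude = list(pair_table = amp_pair, effects = amp_effects),
       feature_sets = sets)
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates a study (unless one is supplied), trains the decoder set on its
#' training session, decodes every test trial, and runs [analyze_decoded()].
#' Recovery is judged by comparing the report's `mean_peak` against
#' `100 * alpha_true`, its identification accuracies against 50%, and its
#' amplitude effect sizes against zero.
#'
#' @param config A [study_config()]; ignored when `study` is given.
#' @param study Optional pre-built [simulate_study()] result.
#' @param area Voxel pool to decode from (`"VC"` = all areas).
#' @param single_identification Also run single-image identification?
#' @return Object of class `recovery_report`: the [analyze_decoded()] fields
#'   plus `alpha_true`, `modulation_mode`, `area`, `layers`,
#'   `mean_peak_overall`, `decoders` and the `config`.
#' @export
run_recovery_experiment <- function(config = study_config(), study = NULL,
                                    area = "VC",
                                    single_identification = TRUE) {
  if (is.null(study)) study <- simulate_study(config)
  config <- study$config
  decoders <- train_decoder_set(study$training$responses,
                                study$training$features,
                                max_voxels = config$max_voxels,
                                area = area, stats = study$stats)
  decoded <- decode_responses(decoders, study$test$responses)
  res <- analyze_decoded(decoded, study$test$trial_table, study$test_images,
                         study$bank, study$stats,
                         grid_step = config$grid_step,
                         feature_set_fraction = config$feature_set_fraction,
                         single_identification = single_identification)
  structure(
    c(list(alpha_true = config$alpha_true,
           modulation_mode = config$modulation_mode,
           area = area, layers = study$bank$layer_names,
           mean_peak_overall = mean(res$mean_peak),
           decoders = decoders, config = config),
      res),
    class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> alpha_true =", sprintf("%.2f", x$alpha_true),
      sprintf("(%s mode), area %s\n", x$modulation_mode, x$area))
  cat(sprintf("  decoding accuracy : %s\n",
              paste(sprintf("%.3f", x$decoding_accuracy), collapse = " ")))
  cat(sprintf("  mean peak contrast: %s (overall %.2f, truth %.0f)\n",
              paste(sprintf("%.1f", x$mean_peak), collapse = " "),
              x$mean_peak_overall, 100 * x$alpha_true))
  cat(sprintf("  identification    : %s %%\n",
              paste(sprintf("%.1f", x$identification$mean_accuracy),
                    collapse = " ")))
  d <- vapply(x$amplitude$effects,
              function(e) if (is.null(e)) NA_real_ else e$d, numeric(1))
  cat(sprintf("  amplitude d       : %s\n",
              paste(sprintf("%.2f", d), collapse = " ")))
  invisible(x)
}
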