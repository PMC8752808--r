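#' Attentional-modulation analyses on decoded feature patterns
#'
#' Three complementary read-outs of attentional modulation, each yielding one
#' statistic per unordered image pair (45 pairs for 10 test images):
#'
#' * **Weighted-contrast peak modeling**: the decoded feature pattern of an
#'   attention trial is correlated, layer by layer, against the stimulus
#'   feature patterns of superpositions of the two pair images over a grid of
#'   attended-image contrast weights; the weight with the highest correlation
#'   (the *peak contrast*) measures the effective stimulus-contrast
#'   equivalent of attention (50 = no modulation).
#' * **Pair-wise identification**: the decoded pattern identifies the
#'   attended image between the two candidates by the larger Pearson
#'   correlation (chance 50%).
#' * **Feature-set amplitude modulation**: mean normalized decoded value over
#'   the attended image's feature set (its top-fraction units from
#'   single-image trials) versus the unattended image's set and the other
#'   images' sets.
#'
#' All correlations are computed on patterns z-scored by the training-set
#' unit statistics.
#'
#' @name modulation
NULL

#' Stimulus feature candidates along a contrast grid
#'
#' Normalized feature patterns of the superpositions of an image pair at each
#' grid weight, oriented so the weight axis is the *attended* image's
#' contrast.
#'
#' @param bank Feature bank.
#' @param image_att,image_unatt The attended / unattended member of the pair.
#' @param grid A [contrast_grid()].
#' @param stats Training [feature_stats] for normalization.
#' @return Named list: per layer, a `length(grid) x n_units` matrix of
#'   normalized candidate patterns.
#' @export
candidate_features <- function(bank, image_att, image_unatt, grid, stats) {
  blends <- lapply(grid, function(w) superimpose(image_att, image_unatt, w))
  normalize_features(extract_feature_matrix(bank, blends), stats)
}

#' Correlation curve of a decoded pattern over contrast weights
#'
#' @param decoded A `layer_features` for one attention trial (raw decoded
#'   values; normalized internally).
#' @param pair Named list of the two component images; names are image ids.
#' @param attended Id of the attended member (must name an entry of `pair`).
#' @param bank,stats Feature bank and training statistics (used to compute
#'   and normalize the candidate patterns).
#' @param grid A [contrast_grid()] (default 5% steps).
#' @param candidates Optional precomputed [candidate_features()] for this
#'   pair and orientation (saves recomputation across the trials of a pair).
#' @return Object of class `contrast_curve`: `grid`, `correlations`
#'   (`length(grid) x n_layers`), `attended`, `pair`. Layers whose normalized
#'   decoded pattern has zero variance are `NA` with a warning.
#' @export
contrast_curve <- function(decoded, pair, attended, bank = NULL, stats,
                           grid = contrast_grid(5), candidates = NULL) {
  assert_that(attended %in% names(pair), "`attended` must name a member of `pair`")
  unatt <- setdiff(names(pair), attended)
  if (length(unatt) != 1) stop_input("`pair` must contain exactly two images")
  if (is.null(candidates)) {
    if (is.null(bank)) stop_input("`bank` is required when `candidates` is NULL")
    candidates <- candidate_features(bank, pair[[attended]], pair[[unatt]],
                                     grid, stats)
  }
  dz <- normalize_features(decoded, stats)
  layers <- names(candidates)
  cors <- vapply(layers, function(l) {
    v <- unclass(dz)[[l]]
    apply(candidates[[l]], 1, function(cand) pattern_cor(v, cand))
  }, numeric(length(grid)))
  cors <- matrix(cors, ncol = length(layers),
                 dimnames = list(NULL, layers))
  if (anyNA(cors))
    warning("contrast_curve: zero-variance pattern; affected layer(s) set to NA")
  structure(list(grid = grid, correlations = cors, attended = attended,
                 pair = names(pair)),
            class = "contrast_curve")
}

#' Peak contrast of a correlation curve
#'
#' Argmax of the correlation over the grid. Exact ties choose the weight
#' closest to 50 (conservative against overstating attentional shift);
#' remaining ties choose the lower weight. An all-equal curve returns the
#' null convention 50 with a message.
#'
#' @param curve A [contrast_curve()].
#' @param layer Layer name or index; `NULL` returns all layers.
#' @return Peak weight(s) in percent.
#' @export
peak_contrast <- function(curve, layer = NULL) {
  pick <- function(r) {
    if (!all(is.finite(r))) return(NA_real_)
    if (max(r) - min(r) == 0) {
      message("peak_contrast: flat curve; returning 50 by convention")
      return(50)
    }
    cand <- which(r == max(r))
    w <- curve$grid[cand]
    w[order(abs(w - 50), w)][1]
  }
  if (is.null(layer)) {
    out <- apply(curve$correlations, 2, pick)
    names(out) <- colnames(curve$correlations)
    out
  } else pick(curve$correlations[, layer])
}

#' Aggregate per-trial peaks into a per-pair summary
#'
#' Averages the peaks of the valid trials of each image pair, pooling both
#' attention conditions (all curves must already be oriented so the weight
#' axis is the attended image's contrast; pooling the two conditions cancels
#' image-saliency bias). Pairs without any valid trial are dropped with a
#' message.
#'
#' @param trial_peaks Data frame with columns `pair` (unordered pair id),
#'   `layer`, `peak`, and logical `valid`.
#' @return Data frame (class `pair_summary`) with one row per pair x layer:
#'   `pair`, `layer`, `mean_peak`, `n_trials`.
#' @export
summarize_peaks <- function(trial_peaks) {
  req <- c("pair", "layer", "peak", "valid")
  assert_that(all(req %in% names(trial_peaks)),
              "`trial_peaks` needs columns pair, layer, peak, valid")
  tp <- trial_peaks[trial_peaks$valid & is.finite(trial_peaks$peak), ]
  dropped <- setdiff(unique(trial_peaks$pair), unique(tp$pair))
  if (length(dropped))
    message("summarize_peaks: no valid trials for pair(s) ",
            paste(dropped, collapse = ", "))
  agg <- stats::aggregate(peak ~ pair + layer, data = tp, FUN = mean)
  n <- stats::aggregate(peak ~ pair + layer, data = tp, FUN = length)
  out <- data.frame(pair = agg$pair, layer = agg$layer,
                    mean_peak = agg$peak, n_trials = n$peak,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_summary", "data.frame")
  out
}

#' Effect size of the peak shift toward the attended image
#'
#' Cohen's d of the per-pair mean peaks against the 50% chance level, with a
#' one-sided t test and 95% CI.
#'
#' @param table A [summarize_peaks()] result.
#' @param layer Layer to evaluate.
#' @param correction Bonferroni factor (e.g. number of layers).
#' @return An [effect_size_result()].
#' @export
peak_shift_effect <- function(table, layer, correction = 1) {
  v <- table$mean_peak[table$layer == layer]
  assert_that(length(v) >= 3, "need >= 3 pairs")
  effect_size_result(v, baseline = 50, correction = correction)
}

#' Pair-wise identification by feature correlation
#'
#' Correlates a decoded pattern with the normalized stimulus patterns of two
#' candidate images and selects the candidate with the higher Pearson r.
#' Exact ties are returned as `"tie"` (scored 0.5 correct downstream);
#' undefined correlations give `NA` (trial excluded).
#'
#' @param decoded `layer_features` of one trial (raw decoded values).
#' @param cand_a,cand_b `layer_features` of the two candidate images
#'   (stimulus-computed, raw).
#' @param stats Training [feature_stats]; all three patterns are normalized
#'   with it.
#' @param layer Layer name or index; `NULL` evaluates all layers.
#' @return Character choice(s): `"a"`, `"b"`, `"tie"`, or `NA`.
#' @export
identify_pairwise <- function(decoded, cand_a, cand_b, stats, layer = NULL) {
  dz <- unclass(normalize_features(decoded, stats))
  az <- unclass(normalize_features(cand_a, stats))
  bz <- unclass(normalize_features(cand_b, stats))
  layers <- if (is.null(layer)) names(dz) else layer
  out <- vapply(layers, function(l) {
    ra <- pattern_cor(dz[[l]], az[[l]])
    rb <- pattern_cor(dz[[l]], bz[[l]])
    if (is.na(ra) || is.na(rb)) return(NA_character_)
    if (ra > rb) "a" else if (rb > ra) "b" else "tie"
  }, character(1))
  if (!is.null(layer) && length(layer) == 1) out[[1]] else out
}

# Score an identification outcome against the correct label ("a"/"b"):
# 1 correct, 0 wrong, 0.5 tie, NA excluded.
identification_score <- function(choice, truth) {
  ifelse(is.na(choice), NA_real_,
         ifelse(choice == "tie", 0.5, as.numeric(choice == truth)))
}

#' Per-pair identification accuracy table
#'
#' Aggregates trial-level identification scores (1 correct / 0 wrong /
#' 0.5 tie) into a per-pair accuracy in percent. In attended mode each
#' attention trial contributes one score to its pair; in single mode each
#' single-image trial contributes one score to each (true, false) pair it was
#' identified against — either way the caller supplies one row per
#' identification.
#'
#' @param scores Data frame with columns `pair`, `layer`, `score` and
#'   optionally logical `valid`.
#' @return Data frame (class `pair_summary`): `pair`, `layer`, `accuracy`
#'   (percent), `n_trials`.
#' @export
identification_table <- function(scores) {
  req <- c("pair", "layer", "score")
  assert_that(all(req %in% names(scores)),
              "`scores` needs columns pair, layer, score")
  if (!is.null(scores$valid)) scores <- scores[scores$valid, ]
  scores <- scores[is.finite(scores$score), ]
  agg <- stats::aggregate(score ~ pair + layer, data = scores, FUN = mean)
  n <- stats::aggregate(score ~ pair + layer, data = scores, FUN = length)
  out <- data.frame(pair = agg$pair, layer = agg$layer,
                    accuracy = 100 * agg$score, n_trials = n$score,
                    stringsAsFactors = FALSE)
  class(out) <- c("pair_summary", "data.frame")
  out
}

#' Effect size of identification accuracy against chance
#'
#' @param table An [identification_table()] result.
#' @param layer Layer to evaluate.
#' @param correction Bonferroni factor.
#' @return An [effect_size_result()] against the 50% chance level.
#' @export
identification_effect <- function(table, layer, correction = 1) {
  v <- table$accuracy[table$layer == layer]
  assert_that(length(v) >= 3, "need >= 3 pairs")
  effect_size_result(v, baseline = 50, correction = correction)
}

#' Image-specific feature sets from single-image trials
#'
#' For each image, the top-fraction units by mean normalized decoded value
#' across that image's single-image trials, per layer. Set size is
#' `ceiling(fraction * n_units)`; ranking ties break by ascending unit index.
#'
#' @param mean_decoded Named list: per layer, an `images x units` matrix of
#'   normalized decoded values averaged across each image's single trials,
#'   with row names = image ids.
#' @param fraction Top fraction in `(0, 1]` (default 0.10).
#' @return Object of class `feature_set`: per layer, a named list of integer
#'   unit-id vectors, one per image.
#' @export
build_feature_sets <- function(mean_decoded, fraction = 0.10) {
  assert_that(fraction > 0 && fraction <= 1, "`fraction` must be in (0, 1]")
  sets <- lapply(mean_decoded, function(M) {
    k <- ceiling(fraction * ncol(M))
    out <- lapply(seq_len(nrow(M)), function(i) {
      v <- M[i, ]
      v[!is.finite(v)] <- -Inf      # degenerate units never selected
      order(-v, seq_along(v))[seq_len(k)]
    })
    names(out) <- rownames(M)
    out
  })
  structure(sets, class = "feature_set", fraction = fraction)
}

#' Amplitude profile of a decoded attention trial over feature sets
#'
#' Mean normalized decoded value over the attended image's feature set, the
#' unattended image's set, and the average of the per-image means over the
#' remaining ("other") images' sets.
#'
#' @param decoded `layer_features` of one attention trial (raw; normalized
#'   internally).
#' @param sets A [build_feature_sets()] result for the same area-layer
#'   combination.
#' @param stats Training [feature_stats].
#' @param attended,unattended Image ids of the pair members.
#' @param others Character vector of the remaining image ids (may be empty,
#'   yielding `NA` for `amp_others`).
#' @return Data frame: one row per layer with `amp_att`, `amp_unatt`,
#'   `amp_others`.
#' @export
amplitude_profile <- function(decoded, sets, stats, attended, unattended,
                              others = character(0)) {
  dz <- unclass(normalize_features(decoded, stats))
  rows <- lapply(names(sets), function(l) {
    v <- dz[[l]]
    set_mean <- function(id) {
      idx <- sets[[l]][[id]]
      if (is.null(idx) || !length(idx)) stop_input(sprintf("empty feature set for image '%s'", id))
      mean(v[idx], na.rm = TRUE)
    }
    amp_o <- if (length(others)) mean(vapply(others, set_mean, numeric(1))) else NA_real_
    data.frame(layer = l, amp_att = set_mean(attended),
               amp_unatt = set_mean(unattended), amp_others = amp_o,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Effect size of attended-vs-unattended amplitude modulation
#'
#' Cohen's d of the per-pair differences `amp_att - amp_unatt` against zero,
#' with one-sided t test and 95% CI.
#'
#' @param table Data frame with one row per pair for a given layer, columns
#'   `amp_att` and `amp_unatt` (e.g. a per-pair aggregation of
#'   [amplitude_profile()] rows).
#' @param correction Bonferroni factor.
#' @return An [effect_size_result()].
#' @export
amplitude_effect <- function(table, correction = 1) {
  d <- table$amp_att - table$amp_unatt
  assert_that(length(d) >= 3, "need >= 3 pairs")
  effect_size_result(d, baseline = 0, correction = correction)
}

#' Aggregate behavioral rating records into per-pair accuracies
#'
#' Pools correctness over trials, raters and (for attention trials) both
#' attention conditions of each unordered pair — pooling cancels pure
#' image-saliency preferences, which produce exactly 50% when a rater always
#' chooses the same member regardless of the attended side.
#'
#' @param records Data frame with columns `pair` (unordered pair id),
#'   `correct` (logical or 0/1), and optionally `trial_id`, `rater`.
#' @param mode `"attended"` or `"single"` (documentation of provenance; the
#'   aggregation is identical).
#' @return Data frame (class `pair_summary`): `pair`, `accuracy` (percent),
#'   `n_records`. Pairs without records are absent (with a message if `mode`
#'   pairs are known via the `pairs` attribute).
#' @export
aggregate_ratings <- function(records, mode = c("attended", "single")) {
  mode <- match.arg(mode)
  assert_that(all(c("pair", "correct") %in% names(records)),
              "`records` needs columns pair, correct")
  agg <- stats::aggregate(correct ~ pair, data = records,
                          FUN = function(v) mean(as.numeric(v)))
  n <- stats::aggregate(correct ~ pair, data = records, FUN = length)
  out <- data.frame(pair = agg$pair, accuracy = 100 * agg$correct,
                    n_records = n$correct, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  class(out) <- c("pair_summary", "data.frame")
  out
}
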