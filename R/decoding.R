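#' Linear feature decoding from multivoxel response patterns
#'
#' One ordinary-least-squares decoder per feature unit, trained on the voxels
#' whose responses correlate most strongly (in absolute value) with that
#' unit's feature values over the training session, with a configurable cap
#' (`max_voxels`, default 500). Decoded and true feature values are compared
#' after z-score normalization by the training-set unit statistics, so that
#' baseline differences between units do not bias pattern correlations.
#'
#' @name decoding
NULL

#' Construct a response matrix
#'
#' @param values Numeric `samples x voxels` matrix.
#' @param voxel_areas Character vector of area labels, one per voxel (e.g.
#'   `"V1"`..`"HVC"`). The special area `"VC"` always denotes the union of
#'   all voxels.
#' @return The matrix with a `voxel_areas` attribute, class `response_matrix`.
#' @export
response_matrix <- function(values, voxel_areas = NULL) {
  values <- as.matrix(values)
  assert_that(all(is.finite(values)), "response values must be finite")
  if (!is.null(voxel_areas)) {
    assert_that(length(voxel_areas) == ncol(values),
                "`voxel_areas` must have one label per voxel")
    attr(values, "voxel_areas") <- as.character(voxel_areas)
  }
  class(values) <- c("response_matrix", class(values))
  values
}

area_columns <- function(X, area) {
  if (is.null(area) || identical(area, "VC")) return(seq_len(ncol(X)))
  labs <- attr(X, "voxel_areas")
  if (is.null(labs)) stop_input("response matrix has no voxel area labels")
  idx <- which(labs == area)
  if (length(idx) == 0) stop_input(sprintf("no voxels labelled '%s'", area))
  idx
}

#' Select voxels by absolute correlation with a feature unit
#'
#' Returns the indices of the voxels with the highest `|r|` against the
#' unit's training feature values, at most `max_voxels` of them, in order of
#' decreasing `|r|` with exact ties broken by ascending voxel index. A
#' zero-variance target marks the unit degenerate: the selection is empty and
#' carries attribute `degenerate = TRUE`.
#'
#' @param X Training `samples x voxels` matrix.
#' @param y Feature values of the target unit, aligned with rows of `X`.
#' @param max_voxels Selection cap (>= 1).
#' @return Integer vector of voxel indices (attribute `degenerate` flags a
#'   constant target).
#' @export
select_voxels <- function(X, y, max_voxels = 500) {
  assert_that(nrow(X) == length(y), "`X` rows must align with `y`")
  assert_that(max_voxels >= 1, "`max_voxels` must be >= 1")
  if (stats::sd(y) == 0)
    return(structure(integer(0), degenerate = TRUE))
  r <- suppressWarnings(as.vector(stats::cor(X, y)))
  r[is.na(r)] <- 0
  idx <- order(-abs(r), seq_along(r))[seq_len(min(max_voxels, ncol(X)))]
  structure(as.integer(idx), degenerate = FALSE)
}

#' Train a full decoder set
#'
#' Fits one least-squares linear regression (with intercept) per feature unit
#' on that unit's selected voxels. Rank-deficient designs fall back to the
#' minimum-norm solution (SVD pseudoinverse) with a note in the log.
#' Degenerate (zero-variance) units get a constant predictor at their
#' training mean and are flagged. The training-set [feature_stats] are stored
#' alongside the decoders for downstream normalization.
#'
#' @param X Training responses: `samples x voxels` matrix, optionally a
#'   [response_matrix()] with area labels.
#' @param features Named list of training feature matrices
#'   (`samples x n_units` per layer).
#' @param max_voxels Per-unit voxel cap (paper-scale default 500).
#' @param area Area whose voxel pool to use; `"VC"` (default) uses all voxels.
#' @param stats Optional precomputed [feature_stats]; computed from
#'   `features` when `NULL`.
#' @return An object of class `decoder_set`.
#' @export
train_decoder_set <- function(X, features, max_voxels = 500, area = "VC",
                              stats = NULL) {
  cols <- area_columns(X, area)
  Xa <- as.matrix(X)[, cols, drop = FALSE]
  n <- nrow(Xa)
  assert_that(all(vapply(features, nrow, 0L) == n),
              "feature matrices must align with response rows")
  if (is.null(stats)) stats <- feature_stats_from_matrix(features)
  k <- min(max_voxels, ncol(Xa))
  any_deficient <- FALSE
  layers <- lapply(features, function(Y) {
    U <- ncol(Y)
    R <- suppressWarnings(stats::cor(Xa, Y))
    R[is.na(R)] <- 0
    sel <- matrix(0L, k, U)
    beta <- matrix(0, k + 1, U)       # row 1 = intercept
    degenerate <- logical(U)
    sdy <- col_sd_pop(Y)
    for (u in seq_len(U)) {
      if (sdy[u] == 0) {
        degenerate[u] <- TRUE
        beta[1, u] <- mean(Y[, u])
        next
      }
      s <- order(-abs(R[, u]), seq_len(ncol(Xa)))[seq_len(k)]
      sel[, u] <- s
      Xs <- cbind(1, Xa[, s, drop = FALSE])
      qrX <- qr(Xs)
      if (qrX$rank < ncol(Xs)) {
        any_deficient <<- TRUE
        beta[, u] <- ols_minnorm(Xs, Y[, u])
      } else {
        beta[, u] <- qr.coef(qrX, Y[, u])
      }
    }
    list(selection = sel, beta = beta, degenerate = degenerate)
  })
  if (any_deficient)
    message("train_decoder_set: rank-deficient design for some units; ",
            "minimum-norm solutions used")
  structure(
    list(area = area, voxel_columns = cols, max_voxels = max_voxels,
         n_train = n, layers = layers, stats = stats),
    class = "decoder_set")
}

#' @export
print.decoder_set <- function(x, ...) {
  cat("<decoder_set> area", x$area, "|", length(x$layers), "layers,",
      sum(vapply(x$layers, function(l) ncol(l$beta), 0L)), "unit decoders,",
      "max", x$max_voxels, "voxels,", x$n_train, "training samples\n")
  invisible(x)
}

#' Decode feature values from response patterns
#'
#' `decode_trial()` decodes a single response vector into a `layer_features`
#' object with provenance `"decoded"`; `decode_responses()` is the batched
#' form over a response matrix.
#'
#' @param decoders A [train_decoder_set()] result.
#' @param x Response vector over the full voxel set used at training.
#' @return `decode_trial()`: a `layer_features`; `decode_responses()`: a
#'   named list of `samples x n_units` matrices.
#' @export
decode_trial <- function(decoders, x) {
  if (length(x) != max(decoders$voxel_columns) && length(x) != length(decoders$voxel_columns))
    stop_input("response vector length does not match the training voxel count")
  D <- decode_responses(decoders, matrix(x, nrow = 1))
  new_layer_features(lapply(D, function(m) m[1, ]), provenance = "decoded")
}

#' @rdname decode_trial
#' @param X Response matrix (`samples x voxels`).
#' @export
decode_responses <- function(decoders, X) {
  X <- as.matrix(X)
  if (ncol(X) >= max(decoders$voxel_columns)) {
    Xa <- X[, decoders$voxel_columns, drop = FALSE]
  } else if (ncol(X) == length(decoders$voxel_columns)) {
    Xa <- X   # already restricted to the decoder's area
  } else stop_input("response matrix does not match the training voxel count")
  lapply(decoders$layers, function(L) {
    U <- ncol(L$beta)
    out <- matrix(0, nrow(Xa), U)
    for (u in seq_len(U)) {
      if (L$degenerate[u]) {
        out[, u] <- L$beta[1, u]
      } else {
        out[, u] <- Xa[, L$selection[, u], drop = FALSE] %*% L$beta[-1, u] +
          L$beta[1, u]
      }
    }
    out
  })
}

#' z-score features by training-set unit statistics
#'
#' Applies `(f - mean) / sd` per unit using the supplied [feature_stats].
#' Degenerate units (zero training SD) are masked to `NA` and excluded from
#' all downstream correlations.
#'
#' @param f A `layer_features` object or a named list of feature matrices.
#' @param stats A [feature_stats] covering the same layers and unit counts.
#' @return Same shape as `f`, normalized.
#' @export
normalize_features <- function(f, stats) {
  is_lf <- inherits(f, "layer_features")
  layers <- if (is_lf) names(unclass(f)) else names(f)
  assert_that(all(layers %in% stats$layers), "stats do not cover all layers")
  norm1 <- function(v, l) {
    mu <- stats$mean[[l]]; sd <- stats$sd[[l]]; deg <- stats$degenerate[[l]]
    if (length(mu) != NCOL(v) && length(mu) != length(v))
      stop_input(sprintf("stats for %s do not match unit count", l))
    if (is.matrix(v)) {
      z <- sweep(sweep(v, 2, mu), 2, ifelse(deg, 1, sd), "/")
      z[, deg] <- NA_real_
      z
    } else {
      z <- (v - mu) / ifelse(deg, 1, sd)
      z[deg] <- NA_real_
      z
    }
  }
  out <- lapply(layers, function(l) norm1(if (is_lf) unclass(f)[[l]] else f[[l]], l))
  names(out) <- layers
  if (is_lf) new_layer_features(out, provenance = attr(f, "provenance")) else out
}

# Pearson r between two unit patterns, skipping NA (degenerate) units.
pattern_cor <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Pattern-correlation decoding accuracy
#'
#' Pearson correlation between the decoded and true unit patterns of each
#' sample, per layer, both normalized with the same training statistics.
#' Samples whose normalized pattern has zero variance yield `NA` with a
#' warning.
#'
#' @param decoded,truth Named lists of feature matrices (`samples x units`),
#'   or `layer_features` for a single sample.
#' @param stats Training [feature_stats] used to normalize both inputs.
#' @return Matrix `samples x layers` of correlations.
#' @export
decoding_accuracy <- function(decoded, truth, stats) {
  as_mat <- function(f)
    if (inherits(f, "layer_features")) lapply(unclass(f), rbind) else f
  D <- normalize_features(as_mat(decoded), stats)
  Tr <- normalize_features(as_mat(truth), stats)
  layers <- names(D)
  out <- vapply(layers, function(l) {
    vapply(seq_len(nrow(D[[l]])), function(i) pattern_cor(D[[l]][i, ], Tr[[l]][i, ]),
           numeric(1))
  }, numeric(nrow(D[[1]])))
  out <- matrix(out, ncol = length(layers), dimnames = list(NULL, layers))
  if (anyNA(out))
    warning("decoding_accuracy: undefined correlations (zero-variance patterns) ",
            "excluded as NA")
  out
}

#' Match decoded feature variances to reference targets
#'
#' Rescales decoded values about the group mean so that the variance across
#' units within each group equals the reference target (one group per layer
#' by default; channel-style groupings can be supplied). Used as the
#' feature-side input correction for reconstruction-type consumers. Groups
#' with zero variance are left unscaled with a warning.
#'
#' @param f A `layer_features` object (decoded values).
#' @param reference_variances Named list: per layer, a single target variance
#'   or one per group.
#' @param groups Optional named list: per layer, an integer/factor grouping
#'   of units. Default: one group spanning the layer.
#' @return The rescaled `layer_features`.
#' @export
variance_match <- function(f, reference_variances, groups = NULL) {
  assert_that(inherits(f, "layer_features"), "`f` must be a layer_features")
  vals <- unclass(f)
  out <- lapply(names(vals), function(l) {
    v <- vals[[l]]
    g <- if (is.null(groups[[l]])) rep(1L, length(v)) else groups[[l]]
    targets <- reference_variances[[l]]
    if (is.null(targets)) stop_input(sprintf("no reference variance for %s", l))
    gl <- sort(unique(g))
    if (length(targets) == 1) targets <- rep(targets, length(gl))
    for (gi in seq_along(gl)) {
      idx <- which(g == gl[gi])
      cur <- stats::var(v[idx]) * (length(idx) - 1) / length(idx)  # population
      if (!is.finite(cur) || cur == 0) {
        warning(sprintf("variance_match: zero within-group variance in %s; group left unscaled", l))
        next
      }
      m <- mean(v[idx])
      v[idx] <- m + (v[idx] - m) * sqrt(targets[gi] / cur)
    }
    v
  })
  names(out) <- names(vals)
  new_layer_features(out, provenance = attr(f, "provenance"))
}
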