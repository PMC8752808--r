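#' Toy stimulus generation and weighted-contrast superposition
#'
#' Images are plain numeric arrays of dimension `height x width x 3` with
#' intensities in `[0, 1]`. [generate_toy_images()] draws procedurally
#' generated colored shapes and band-limited textures; [superimpose()] forms
#' the weighted-contrast blend of an image pair used throughout the
#' attentional-modulation analyses; [contrast_grid()] builds the grid of
#' attended-image contrast weights on which peak modulation is estimated.
#'
#' @name stimuli
NULL

validate_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_input(sprintf("`%s` must be a height x width x 3 array", arg))
  if (!all(is.finite(img)))
    stop_input(sprintf("`%s` contains non-finite values", arg))
  invisible(img)
}

# One dictionary pattern: a colored rectangle, disc, or band-limited texture
# on a mid-gray background; values in [0, 1].
make_pattern <- function(size) {
  type <- sample(c("rect", "disc", "texture"), 1)
  col <- runif(3)
  img <- array(0.5, c(size, size, 3))
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  if (type == "rect") {
    x0 <- sort(sample(seq_len(size), 2))
    y0 <- sort(sample(seq_len(size), 2))
    mask <- xs >= x0[1] & xs <= x0[2] & ys >= y0[1] & ys <= y0[2]
  } else if (type == "disc") {
    cx <- runif(1, size * 0.2, size * 0.8)
    cy <- runif(1, size * 0.2, size * 0.8)
    r <- runif(1, size * 0.1, size * 0.35)
    mask <- (xs - cx)^2 + (ys - cy)^2 <= r^2
  } else {
    wavelength <- sample(3:9, 1)
    k <- rep(1, wavelength) / wavelength
    for (c in 1:3) {
      z <- matrix(rnorm(size * size), size, size)
      z <- apply(z, 2, function(v) stats::filter(v, k, circular = TRUE))
      z <- t(apply(z, 1, function(v) stats::filter(v, k, circular = TRUE)))
      z <- (z - min(z)) / (max(z) - min(z))
      img[, , c] <- 0.5 * (1 - col[c]) + z * col[c]
    }
    return(img)
  }
  for (c in 1:3) {
    m <- img[, , c]
    m[mask] <- col[c]
    img[, , c] <- m
  }
  img
}

#' Generate a set of toy stimulus images
#'
#' Draws a dictionary of `n_patterns` colored shapes and band-limited textures
#' and returns `n` distinct convex mixtures of it. All returned images share
#' the same dictionary, so the whole set spans a low-dimensional affine family
#' of pixel space; their root-mean-square deviation from the family mean
#' ("RMS contrast") is matched across images, the standard stimulus-matching
#' practice that keeps any one image from dominating pattern correlations by
#' sheer contrast.
#'
#' @param n Number of images (>= 1).
#' @param size Image side length in pixels (images are `size x size x 3`).
#' @param seed Integer seed; the returned list is bit-reproducible given
#'   `(n, size, seed, n_patterns)`.
#' @param n_patterns Dictionary size; the latent dimensionality of the family.
#' @return List of `n` arrays `size x size x 3` with values in `[0, 1]`.
#' @export
#' @examples
#' imgs <- generate_toy_images(3, size = 32, seed = 1)
#' range(imgs[[1]])
generate_toy_images <- function(n, size = 64, seed = 1, n_patterns = 20) {
  assert_that(is.numeric(n) && length(n) == 1 && n >= 1, "`n` must be >= 1")
  assert_that(size >= 8, "`size` must be >= 8 pixels")
  with_seed(seed, {
    dict <- vapply(seq_len(n_patterns), function(i) as.vector(make_pattern(size)),
                   numeric(size * size * 3))
    mu <- rowMeans(dict)
    # target RMS contrast: median over probe mixtures, slightly shrunk so the
    # rescaled images stay inside [0, 1] without clipping
    probe <- replicate(32, {
      w <- rexp(n_patterns)^2; w <- w / sum(w)
      d <- as.vector(dict %*% w) - mu
      sqrt(mean(d * d))
    })
    target <- stats::median(probe)
    lapply(seq_len(n), function(i) {
      w <- rexp(n_patterns)^2; w <- w / sum(w)
      d <- as.vector(dict %*% w) - mu
      s <- target / sqrt(mean(d * d))
      # largest scale keeping mu + s*d within [0, 1]
      sbound <- suppressWarnings(min(
        c(mu[d < 0] / -d[d < 0], (1 - mu[d > 0]) / d[d > 0])))
      x <- mu + min(s, sbound) * d
      array(x, c(size, size, 3))
    })
  })
}

#' Superimpose two images with weighted contrast
#'
#' Pixel-wise convex combination `S = (w/100) * a + (1 - w/100) * b`, so that
#' `w` is the contrast weight of image `a` in percent. `w = 50` reproduces the
#' equally-weighted stimulus shown in attention trials.
#'
#' @param a,b Images of identical shape (`height x width x 3`, values in
#'   `[0, 1]`).
#' @param w Contrast weight of `a`, in percent (`0 <= w <= 100`).
#' @return The blended image.
#' @export
superimpose <- function(a, b, w) {
  validate_image(a, "a"); validate_image(b, "b")
  if (!identical(dim(a), dim(b))) stop_input("`a` and `b` have different shapes")
  assert_that(is.numeric(w) && length(w) == 1 && w >= 0 && w <= 100,
              "`w` must be a single weight in [0, 100]")
  (w / 100) * a + (1 - w / 100) * b
}

#' Contrast-weight grid
#'
#' Ordered attended-image contrast weights `0, step, ..., 100` (percent). The
#' default 5% step gives the 21-point grid on which peak modulation is read
#' out.
#'
#' @param step Grid step in percent; must divide 100.
#' @return Numeric vector of weights, strictly increasing, symmetric about 50.
#' @export
contrast_grid <- function(step = 5) {
  assert_that(is.numeric(step) && length(step) == 1 && step > 0,
              "`step` must be a positive number")
  if (100 %% step != 0) stop_input("`step` must divide 100")
  seq(0, 100, by = step)
}

# Bilinear resize of an image to size_out x size_out (used when a feature
# bank expects a different input geometry than the supplied image).
resize_image <- function(img, size_out) {
  validate_image(img)
  d <- dim(img)
  if (d[1] == size_out && d[2] == size_out) return(img)
  out <- array(0, c(size_out, size_out, 3))
  # map output pixel centers onto input coordinates
  sx <- (seq_len(size_out) - 0.5) * d[1] / size_out + 0.5
  sy <- (seq_len(size_out) - 0.5) * d[2] / size_out + 0.5
  x0 <- pmin(pmax(floor(sx), 1), d[1]); x1 <- pmin(x0 + 1, d[1])
  y0 <- pmin(pmax(floor(sy), 1), d[2]); y1 <- pmin(y0 + 1, d[2])
  fx <- pmin(pmax(sx - x0, 0), 1); fy <- pmin(pmax(sy - y0, 0), 1)
  for (c in 1:3) {
    m <- img[, , c]
    out[, , c] <-
      outer(1 - fx, 1 - fy) * m[x0, y0] + outer(fx, 1 - fy) * m[x1, y0] +
      outer(1 - fx, fy) * m[x0, y1] + outer(fx, fy) * m[x1, y1]
  }
  out
}
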