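#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic package operations route
# through this so that a user's RNG stream is never disturbed.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stop_input <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop_input(msg)

# Minimum-norm least squares: solves argmin ||X b - y||, returning the
# minimum-norm solution when X is rank deficient (SVD pseudoinverse).
# y may be a matrix (one solve per column).
ols_minnorm <- function(X, y, tol = 1e-10) {
  sv <- svd(X)
  keep <- sv$d > sv$d[1] * tol
  if (!any(keep)) return(matrix(0, ncol(X), NCOL(y)))
  uy <- crossprod(sv$u[, keep, drop = FALSE], as.matrix(y))
  sv$v[, keep, drop = FALSE] %*% (uy / sv$d[keep])
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used to stamp
# configurations into run metadata without an external digest dependency.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor into the low byte (kept in double arithmetic to avoid 32-bit
    # integer overflow), then 32-bit modular multiply by the FNV prime
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536; hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Column-wise population standard deviation (divide by n).
col_sd_pop <- function(M) {
  n <- nrow(M)
  mu <- colMeans(M)
  sqrt(pmax(colMeans(M * M) - mu * mu, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
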