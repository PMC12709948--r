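# Internal helpers: seeding, clipping, Gaussian filtering.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# FNV-1a hash of a string, folded into a positive 31-bit integer.
fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261 %% 2147483647
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# Stage-specific sub-seed derived from a master seed, kept below 2^31.
derive_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + fnv1a(tag)) %% 2147483647)
}

# 1D Gaussian kernel, radius 3*sigma.
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur of a matrix with edge renormalisation (truncated
# kernels at the borders are rescaled to sum to one).
gauss_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- gauss_kernel(sigma)
  Mr <- conv_band_matrix(nrow(x), k, renormalize = TRUE)
  Mc <- conv_band_matrix(ncol(x), k, renormalize = TRUE)
  Mr %*% x %*% t(Mc)
}

# n_out x n convolution operator matrix for a centered 1D kernel.
# renormalize = TRUE keeps 'same' size with rescaled truncated edges;
# renormalize = FALSE returns the 'valid' operator ((n - 2r) x n rows).
conv_band_matrix <- function(n, k, renormalize = TRUE) {
  r <- (length(k) - 1L) %/% 2L
  if (renormalize) {
    M <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      M[i, j[ok]] <- k[ok] / sum(k[ok])
    }
  } else {
    stopifnot(n >= 2 * r + 1)
    M <- matrix(0, n - 2L * r, n)
    for (i in seq_len(n - 2L * r)) M[i, i:(i + 2L * r)] <- k
  }
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
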