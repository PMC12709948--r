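# Independent brute-force oracles: scalar per-pixel loops, no shared code
# with the implementations they check.

oracle_mse <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  s / length(x)
}

oracle_psnr <- function(x, y, max_value = 1, cap = 100) {
  m <- oracle_mse(x, y)
  if (m == 0) return(cap)
  min(10 * log10(max_value^2 / m), cap)
}

oracle_mrae <- function(x, y, eps = 1 / 255) {
  s <- 0
  for (i in seq_along(x)) s <- s + abs(x[i] - y[i]) / max(y[i], eps)
  s / length(x)
}

# Windowed SSIM by explicit window loops (valid region, 11x11 Gaussian).
oracle_ssim <- function(x, y, max_value = 1) {
  r <- 5L
  g1 <- exp(-(-r:r)^2 / (2 * 1.5^2)); g1 <- g1 / sum(g1)
  w <- outer(g1, g1)
  c1 <- (0.01 * max_value)^2; c2 <- (0.03 * max_value)^2
  vals <- c()
  for (ci in (r + 1):(nrow(x) - r)) for (cj in (r + 1):(ncol(x) - r)) {
    xs <- x[(ci - r):(ci + r), (cj - r):(cj + r)]
    ys <- y[(ci - r):(ci + r), (cj - r):(cj + r)]
    mx <- sum(w * xs); my <- sum(w * ys)
    vx <- sum(w * xs^2) - mx^2; vy <- sum(w * ys^2) - my^2
    vxy <- sum(w * xs * ys) - mx * my
    vals <- c(vals, (2 * mx * my + c1) * (2 * vxy + c2) /
                ((mx^2 + my^2 + c1) * (vx + vy + c2)))
  }
  mean(vals)
}

oracle_vi <- function(ci, cj, eps) {
  out <- ci
  for (k in seq_along(ci)) out[k] <- (ci[k] - cj[k]) / (ci[k] + cj[k] + eps)
  out
}

oracle_weight_fuse <- function(bands255, w) {
  out <- bands255[, , 1] * 0
  for (i in seq_len(nrow(out))) for (j in seq_len(ncol(out))) {
    s <- 0
    for (b in 1:4) s <- s + w[b] * bands255[i, j, b]
    out[i, j] <- min(max(s, 0), 255)
  }
  out
}

oracle_miou <- function(pred, gt) {
  ious <- c()
  for (cls in 0:1) {
    inter <- sum(pred == cls & gt == cls)
    uni <- sum(pred == cls | gt == cls)
    ious <- c(ious, if (uni == 0) 1 else inter / uni)
  }
  mean(ious)
}

# Count patch tiles by explicit enumeration.
oracle_patch_count <- function(H, W, p) {
  n <- 0L
  i <- 1
  while (i + p - 1 <= H) {
    j <- 1
    while (j + p - 1 <= W) { n <- n + 1L; j <- j + p }
    i <- i + p
  }
  n
}

# Integer-pixel cross-correlation peak between two matrices: returns the
# (dy, dx) shift of b relative to a maximising overlap correlation.
oracle_xcorr_offset <- function(a, b, max_shift = 5L) {
  best <- c(0, 0); bestv <- -Inf
  H <- nrow(a); W <- ncol(a)
  for (dy in -max_shift:max_shift) for (dx in -max_shift:max_shift) {
    ia <- max(1, 1 + dy):min(H, H + dy)
    ja <- max(1, 1 + dx):min(W, W + dx)
    ib <- ia - dy; jb <- ja - dx
    v <- stats::cor(as.vector(a[ia, ja]), as.vector(b[ib, jb]))
    if (!is.na(v) && v > bestv) { bestv <- v; best <- c(dy, dx) }
  }
  best
}

# Small random image helpers (quantised to the 8-bit grid when asked, so
# byte round-trips are exact).
rand_raster <- function(H, W, C, quantize = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- array(stats::runif(H * W * C), c(H, W, C))
  if (quantize) a <- round(a * 255) / 255
  a
}
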