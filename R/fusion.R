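# Band fusion: collapse a 4-band spectral image (or an RGB channel pair)
# into one scalar index map ahead of thresholding.

fused_map <- function(values, scale, config) {
  structure(list(values = values, scale = scale, config = config),
            class = "fused_map")
}

#' @export
print.fused_map <- function(x, ...) {
  cat(sprintf("<fused_map %dx%d, %s scale, range [%.3f, %.3f]>\n",
              nrow(x$values), ncol(x$values), x$scale,
              min(x$values), max(x$values)))
  invisible(x)
}

band_index <- function(band) {
  if (is.character(band)) {
    i <- match(band, names(VEGSR_BANDS))
    if (is.na(i)) stop("unknown band name: ", band)
    i
  } else as.integer(band)
}

#' Vegetation-index fusion of two spectral bands
#'
#' Per pixel `(C_i - C_j) / (C_i + C_j + epsilon)`, the generic
#' normalized-difference form.  The default pair puts NIR in the numerator
#' lead and green as the contrast band, so vegetation comes out positive
#' (the classic "index > 0 means vegetation cover" reading).
#'
#' @param spectral a [spectral_image()] on the unit scale.
#' @param band_i,band_j band names (`"green"`, `"red"`, `"red_edge"`,
#'   `"nir"`) or indices 1..4; must differ.
#' @param epsilon denominator stabiliser for dark pixels.
#' @return a `fused_map` with scale `"vi"` (values in `[-1, 1]` for
#'   non-negative inputs).
#' @export
fuse_vi <- function(spectral, band_i = "nir", band_j = "green",
                    epsilon = 1e-6) {
  stopifnot(epsilon > 0)
  i <- band_index(band_i); j <- band_index(band_j)
  if (i == j) stop("band_i and band_j must differ")
  a <- px(spectral)
  ci <- a[, , i]; cj <- a[, , j]
  fused_map((ci - cj) / (ci + cj + epsilon), "vi",
            list(strategy = "vi", band_i = band_i, band_j = band_j,
                 epsilon = epsilon))
}

#' Weighted-sum fusion of the four spectral bands
#'
#' Per pixel `sum_i W_i * C_i`, computed on the byte scale (`C_i` in
#' `[0, 255]`) and clipped to `[0, 255]` — the scale on which the adaptive
#' threshold bounds (145/150) are defined.  The default weights
#' `c(-1, 0, 1, 1)` subtract green and add red-edge and NIR.
#'
#' @param spectral a [spectral_image()] on the unit scale.
#' @param weights numeric vector of 4 band weights (green, red, red_edge,
#'   nir).
#' @return a `fused_map` with scale `"weight"` (values in `[0, 255]`).
#' @export
fuse_weight <- function(spectral, weights = c(-1, 0, 1, 1)) {
  if (length(weights) != 4L) stop("`weights` must have length 4")
  a <- px(spectral) * 255
  v <- weights[1] * a[, , 1] + weights[2] * a[, , 2] +
    weights[3] * a[, , 3] + weights[4] * a[, , 4]
  fused_map(pmin(pmax(v, 0), 255), "weight",
            list(strategy = "weight", weights = weights))
}

#' Vegetation-index fusion of an RGB channel pair (ablation mode)
#'
#' Applies the normalized-difference form directly to two RGB channels,
#' skipping spectral reconstruction entirely: the first named channel is
#' the numerator lead (e.g. `"GB"` gives `(G - B)/(G + B)`).
#'
#' @param rgb an [rgb_image()] on the unit scale.
#' @param pair one of `"GB"`, `"RB"`, `"RG"`.
#' @inheritParams fuse_vi
#' @return a `fused_map` with scale `"vi"`.
#' @export
fuse_rgb_pair <- function(rgb, pair = c("GB", "RB", "RG"), epsilon = 1e-6) {
  pair <- match.arg(pair)
  a <- px(rgb)
  chan <- c(R = 1L, G = 2L, B = 3L)
  i <- chan[[substr(pair, 1, 1)]]
  j <- chan[[substr(pair, 2, 2)]]
  ci <- a[, , i]; cj <- a[, , j]
  fused_map((ci - cj) / (ci + cj + epsilon), "vi",
            list(strategy = "rgb_pair", pair = pair, epsilon = epsilon))
}
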