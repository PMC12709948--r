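# Synthetic paired field scenes: RGB + 4-band multispectral + ground-truth
# mask, with an optional per-band rigid misalignment emulating the residual
# registration error of multi-lens UAV sensors ("strong noise").

#' Default per-class spectral signatures of the synthetic scenes
#'
#' Mean reflectances for the three scene classes (vegetation, bare soil,
#' plastic mulch film) in the four multispectral bands (green, red,
#' red_edge, nir) and as an RGB rendering, plus a per-channel
#' multiplicative jitter scale.  The values are synthetic: they are
#' calibrated to the qualitative red-edge/NIR rise of healthy vegetation
#' against flat soil/film spectra, such that the normalized-difference
#' index (nir - green)/(nir + green) is strongly positive for vegetation
#' (about +0.69) and slightly negative for soil (about -0.11) and film.
#'
#' @return a named list of class signatures, each with elements `ms` (4
#'   reflectances), `rgb` (3 reflectances) and `jitter_sd`.
#' @export
default_signatures <- function() {
  list(
    vegetation = list(ms = c(green = 0.10, red = 0.06, red_edge = 0.45, nir = 0.55),
                      rgb = c(r = 0.12, g = 0.30, b = 0.10), jitter_sd = 0.03),
    soil = list(ms = c(green = 0.31, red = 0.35, red_edge = 0.33, nir = 0.25),
                rgb = c(r = 0.45, g = 0.35, b = 0.28), jitter_sd = 0.03),
    film = list(ms = c(green = 0.60, red = 0.60, red_edge = 0.62, nir = 0.62),
                rgb = c(r = 0.75, g = 0.75, b = 0.78), jitter_sd = 0.03)
  )
}

#' Parameters of a synthetic field scene
#'
#' @param height,width scene size in pixels (>= 16).
#' @param layout `"dense"` (closed canopy, e.g. sorghum), `"row_crop"`
#'   (plants along periodic rows, e.g. pepper) or `"mixed"`.
#' @param target_veg_fraction fraction of pixels that should be vegetation;
#'   enforced per scene through the empirical quantile of the underlying
#'   random field.
#' @param blob_scale correlation length of the vegetation pattern, pixels.
#' @param film_fraction fraction of all pixels covered by plastic mulch
#'   film (laid on background only).
#' @param illumination_gain global multiplicative illumination factor.
#' @param pixel_noise_sd additive Gaussian noise sd on the unit scale
#'   (sensor noise plus unmodelled within-class texture).
#' @param strong_noise_px maximum per-band translation magnitude in pixels
#'   applied to the multispectral raster (0 disables it).
#' @param seed integer seed; scenes are bitwise reproducible under it.
#' @return a list of class `scene_spec`.
#' @export
scene_spec <- function(height = 64L, width = 64L,
                       layout = c("dense", "row_crop", "mixed"),
                       target_veg_fraction = 0.3, blob_scale = 6,
                       film_fraction = 0, illumination_gain = 1,
                       pixel_noise_sd = 0.05, strong_noise_px = 0,
                       seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(height >= 16L, width >= 16L,
            target_veg_fraction >= 0, target_veg_fraction <= 1,
            film_fraction >= 0, film_fraction <= 1,
            illumination_gain > 0, pixel_noise_sd >= 0, strong_noise_px >= 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 layout = layout, target_veg_fraction = target_veg_fraction,
                 blob_scale = blob_scale, film_fraction = film_fraction,
                 illumination_gain = illumination_gain,
                 pixel_noise_sd = pixel_noise_sd,
                 strong_noise_px = strong_noise_px, seed = as.integer(seed)),
            class = "scene_spec")
}

# Class map: 1 vegetation, 2 soil, 3 film.
scene_class_map <- function(spec) {
  H <- spec$height; W <- spec$width
  sigma <- max(spec$blob_scale / 2, 0.75)
  field <- gauss_blur(matrix(stats::rnorm(H * W), H, W), sigma)
  field <- (field - mean(field)) / (stats::sd(field) + 1e-12)
  if (spec$layout != "dense") {
    period <- max(4 * spec$blob_scale, 8)
    rows <- matrix(cos(2 * pi * col(field) / period), H, W)
    gain <- if (spec$layout == "row_crop") 2 else 1
    field <- field + gain * rows
  }
  f <- spec$target_veg_fraction
  veg <- if (f <= 0) matrix(FALSE, H, W)
         else if (f >= 1) matrix(TRUE, H, W)
         else field > stats::quantile(field, 1 - f)
  cls <- matrix(2L, H, W)
  cls[veg] <- 1L
  if (spec$film_fraction > 0 && any(!veg)) {
    ff <- gauss_blur(matrix(stats::rnorm(H * W), H, W), max(sigma * 2, 2))
    want <- min(spec$film_fraction * H * W, sum(!veg))
    qf <- stats::quantile(ff[!veg], 1 - want / sum(!veg))
    cls[!veg & ff > qf] <- 3L
  }
  cls
}

# Render one channel stack from per-class means.
render_channels <- function(cls, means, jitter, gain, noise_sd) {
  H <- nrow(cls); W <- ncol(cls); nc <- ncol(means)
  out <- array(0, c(H, W, nc))
  base <- means[cls, , drop = FALSE] # (H*W) x nc
  for (c in seq_len(nc)) {
    v <- base[, c] * gain *
      (1 + stats::rnorm(H * W) * jitter[cls]) +
      stats::rnorm(H * W) * noise_sd
    out[, , c] <- matrix(clip01(v), H, W)
  }
  out
}

#' Generate one synthetic paired field scene
#'
#' Draws a class map (vegetation / soil / film) by thresholding a smoothed
#' Gaussian random field (optionally modulated by periodic crop rows) at
#' the quantile matching `target_veg_fraction`, then renders a paired RGB
#' and 4-band multispectral raster from the per-class signatures with
#' multiplicative jitter and additive pixel noise.  If
#' `spec$strong_noise_px > 0`, a misaligned copy of the spectral raster is
#' produced with [inject_strong_noise()].
#'
#' @param spec a [scene_spec()].
#' @param signatures per-class signatures, see [default_signatures()].
#' @return a list of class `synthetic_sample` with elements `rgb`,
#'   `spectral_clean`, `spectral_noisy`, `mask`, `spec`.
#' @export
generate_scene <- function(spec, signatures = default_signatures()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    cls <- scene_class_map(spec)
    ms_means <- do.call(rbind, lapply(signatures, function(s) s$ms))
    rgb_means <- do.call(rbind, lapply(signatures, function(s) s$rgb))
    jit <- vapply(signatures, function(s) s$jitter_sd, numeric(1))
    ms <- render_channels(cls, ms_means, jit, spec$illumination_gain,
                          spec$pixel_noise_sd)
    rgb <- render_channels(cls, rgb_means, jit, spec$illumination_gain,
                           spec$pixel_noise_sd)
    id <- sprintf("scene%08d", spec$seed)
    sample <- structure(list(
      rgb = rgb_image(rgb, id = id),
      spectral_clean = spectral_image(ms, id = id),
      spectral_noisy = spectral_image(ms, id = id),
      mask = binary_mask((cls == 1L) * 1L, id = id),
      spec = spec), class = "synthetic_sample")
    if (spec$strong_noise_px > 0)
      sample <- inject_strong_noise(sample, spec$strong_noise_px,
                                    seed = derive_seed(spec$seed, "strong_noise"))
    sample
  })
}

# Translate a matrix by a continuous offset (dy, dx) with bilinear
# resampling and edge replication: out(i, j) = in(i - dy, j - dx).
translate_bilinear <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  si <- pmin(pmax(row(m) - dy, 1), H)
  sj <- pmin(pmax(col(m) - dx, 1), W)
  i0 <- pmin(floor(si), H - 1); j0 <- pmin(floor(sj), W - 1)
  wi <- si - i0; wj <- sj - j0
  idx <- function(i, j) m[cbind(as.vector(i), as.vector(j))]
  v <- (1 - wi) * (1 - wj) * idx(i0, j0) +
       wi * (1 - wj) * idx(i0 + 1, j0) +
       (1 - wi) * wj * idx(i0, j0 + 1) +
       wi * wj * idx(i0 + 1, j0 + 1)
  matrix(v, H, W)
}

#' Inject per-band spatial misalignment ("strong noise")
#'
#' Each multispectral band is independently translated by a random
#' continuous offset with `|dx|, |dy| <= magnitude_px` (bilinear
#' resampling, edge replication), emulating residual registration error
#' between the lenses of a multi-camera UAV sensor.  The RGB raster and
#' the mask are untouched; magnitude 0 is the identity.
#'
#' @param sample a `synthetic_sample`.
#' @param magnitude_px maximum offset magnitude in pixels (>= 0).
#' @param seed integer seed for the offset draw.
#' @return the sample with `spectral_noisy` replaced; the drawn offsets are
#'   attached as attribute `"offsets"` (4 x 2 matrix, columns dy, dx).
#' @export
inject_strong_noise <- function(sample, magnitude_px, seed = 1L) {
  stopifnot(magnitude_px >= 0)
  a <- sample$spectral_clean$pixels
  if (magnitude_px == 0) {
    sample$spectral_noisy <- sample$spectral_clean
    return(sample)
  }
  off <- with_seed(seed,
                   matrix(stats::runif(8, -magnitude_px, magnitude_px), 4, 2))
  colnames(off) <- c("dy", "dx")
  out <- a
  for (b in 1:4) out[, , b] <- translate_bilinear(a[, , b], off[b, 1], off[b, 2])
  noisy <- spectral_image(out, id = sample$spectral_clean$id)
  attr(noisy, "offsets") <- off
  sample$spectral_noisy <- noisy
  sample
}

#' Generate a synthetic dataset on disk with a train/test manifest
#'
#' Draws `n` scene specs uniformly from `spec_ranges` (each entry a scalar
#' or a `c(lo, hi)` range), renders the scenes, writes RGB (PNG),
#' multispectral (4-page TIFF; the misaligned raster when strong noise is
#' on, as a real sensor would deliver) and mask (PNG) files under
#' `out_dir`, and returns a manifest with a `ratio` train/test split.
#'
#' @param n number of scenes (>= 2).
#' @param out_dir output directory (created if needed).
#' @param spec_ranges named list overriding [scene_spec()] arguments.
#' @param ratio train fraction for [split_dataset()].
#' @param seed master seed.
#' @return a `vegsr_manifest` (also written to `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(n, out_dir, spec_ranges = list(), ratio = 0.9,
                             seed = 1L) {
  stopifnot(n >= 2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- simulate_scenes(n, spec_ranges, seed)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    id <- sprintf("s%04d", i)
    paths <- c(rgb = file.path(out_dir, paste0(id, "_rgb.png")),
               ms = file.path(out_dir, paste0(id, "_ms.tif")),
               mask = file.path(out_dir, paste0(id, "_mask.png")))
    write_rgb(s$rgb, paths["rgb"])
    write_spectral(s$spectral_noisy, paths["ms"])
    write_mask(s$mask, paths["mask"])
    data.frame(id = id, rgb = paths["rgb"], spectral = paths["ms"],
               mask = paths["mask"], split = NA_character_,
               stringsAsFactors = FALSE)
  })
  m <- do.call(rbind, rows)
  class(m) <- c("vegsr_manifest", "data.frame")
  m <- split_dataset(m, ratio = ratio, seed = derive_seed(seed, "split"))
  write_manifest(m, file.path(out_dir, "manifest.csv"))
  m
}

#' Generate a list of in-memory synthetic scenes
#'
#' Same sampling scheme as [generate_dataset()] but without touching disk.
#'
#' @inheritParams generate_dataset
#' @param signatures per-class signatures, see [default_signatures()].
#' @return a list of `synthetic_sample` objects.
#' @export
simulate_scenes <- function(n, spec_ranges = list(), seed = 1L,
                            signatures = default_signatures()) {
  draws <- with_seed(derive_seed(seed, "specs"), {
    lapply(seq_len(n), function(i) {
      args <- lapply(spec_ranges, function(v) {
        if (is.numeric(v) && length(v) == 2L) stats::runif(1, v[1], v[2]) else v
      })
      args$seed <- derive_seed(seed, paste0("scene", i))
      do.call(scene_spec, args)
    })
  })
  lapply(draws, generate_scene, signatures = signatures)
}
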