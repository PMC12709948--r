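# Raster readers/writers.  RGB as PNG or TIFF; multispectral as 4-page
# grayscale TIFF (page order = band order green, red, red_edge, nir);
# masks as single-channel PNG with {0, 255} on disk.

file_ext <- function(path) tolower(sub(".*\\.", "", path))

#' Read an RGB image (PNG or TIFF)
#'
#' @param path path to a 3-channel PNG or TIFF file.
#' @return an [rgb_image()] on the unit scale.
#' @export
read_rgb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- file_ext(path)
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported RGB format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(a)) != 3L || dim(a)[3] != 3L)
    stop("expected a 3-channel image, got ",
         if (length(dim(a)) == 3L) dim(a)[3] else 1L, " channel(s)")
  rgb_image(a, scale = "unit", id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write an RGB image as an 8-bit PNG
#'
#' @param img an [rgb_image()].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_rgb <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  png::writePNG(to_unit(img)$pixels, path)
  invisible(path)
}

#' Read a 4-band multispectral image from a multi-page TIFF
#'
#' Accepts either a 4-page grayscale TIFF (the package's own convention,
#' page order green, red, red_edge, nir) or a single-page 4-channel TIFF.
#'
#' @param path path to the TIFF file.
#' @return a [spectral_image()] on the unit scale.
#' @export
read_spectral <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    a <- pages[[1]]
    if (dim(a)[3] != 4L) stop("expected 4 bands, got ", dim(a)[3])
  } else {
    if (length(pages) != 4L)
      stop("expected a 4-page TIFF, got ", length(pages), " page(s)")
    if (any(vapply(pages, function(p) length(dim(p)) != 2L, logical(1))))
      stop("multi-page spectral TIFF must hold grayscale pages")
    a <- array(unlist(pages), c(dim(pages[[1]]), 4L))
  }
  spectral_image(a, scale = "unit", id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a 4-band multispectral image as a multi-page grayscale TIFF
#'
#' @param img a [spectral_image()].
#' @param path output path (.tif/.tiff).
#' @param bits bits per sample: 8 or 16 for integer data, 32 for float.
#' @return `path`, invisibly.
#' @export
write_spectral <- function(img, path, bits = 8L) {
  stopifnot(inherits(img, "spectral_image"))
  a <- to_unit(img)$pixels
  pages <- lapply(1:4, function(b) a[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

#' Read a binary mask from a PNG ({0, 255} on disk -> {0, 1} in memory)
#'
#' @param path path to a single-channel PNG.
#' @return a [binary_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  binary_mask((a > 0.5) * 1L, id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a binary mask as a viewable PNG ({0, 1} -> {0, 255})
#'
#' @param mask a [binary_mask()].
#' @param path output path (.png).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  png::writePNG(mask$labels * 1.0, path)
  invisible(path)
}

#' Extract all non-overlapping square patches from an image
#'
#' Tiles the raster on a regular grid anchored at the top-left corner, in
#' row-major order; residual right/bottom borders that do not fill a whole
#' patch are discarded, so the patch count is
#' `floor(H / patch_size) * floor(W / patch_size)`.
#'
#' @param image an [rgb_image()], [spectral_image()], [binary_mask()] or a
#'   plain matrix/array.
#' @param patch_size side length in pixels (>= 1).
#' @return a list of objects of the same class as `image`.
#' @examples
#' img <- rgb_image(array(0, c(1280, 960, 3)))
#' length(extract_patches(img, 340))  # 6 patches, the UAV sensor geometry
#' @export
extract_patches <- function(image, patch_size) {
  stopifnot(patch_size >= 1)
  patch_size <- as.integer(patch_size)
  a <- px(image)
  d <- dim(a)
  nh <- d[1] %/% patch_size
  nw <- d[2] %/% patch_size
  if (nh < 1L || nw < 1L) return(list())
  out <- vector("list", nh * nw)
  k <- 0L
  for (i in seq_len(nh)) for (j in seq_len(nw)) {
    k <- k + 1L
    ri <- ((i - 1L) * patch_size + 1L):(i * patch_size)
    cj <- ((j - 1L) * patch_size + 1L):(j * patch_size)
    sub <- if (length(d) == 3L) a[ri, cj, , drop = FALSE] else a[ri, cj, drop = FALSE]
    out[[k]] <- rewrap(image, sub, suffix = sprintf("p%02d", k))
  }
  out
}

# Rebuild an object of the same class as `template` around new pixel data.
rewrap <- function(template, a, suffix = NULL) {
  id <- if (is.list(template) && !is.null(template$id) && !is.null(suffix))
    paste(template$id, suffix, sep = "_") else suffix
  if (inherits(template, "rgb_image")) rgb_image(a, template$scale, id)
  else if (inherits(template, "spectral_image")) spectral_image(a, template$scale, id)
  else if (inherits(template, "binary_mask")) binary_mask(a, id)
  else a
}
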