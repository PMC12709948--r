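#' RGB image container
#'
#' A light wrapper around an `H x W x 3` numeric array with a declared value
#' scale.  All package internals compute on the unit scale `[0, 1]`; byte
#' data (`[0, 255]`) is accepted and can be converted with [to_unit()].
#'
#' @param pixels numeric `H x W x 3` array, channel order R, G, B.
#' @param scale `"unit"` or `"byte"`.
#' @param id optional sample identifier.
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, scale = c("unit", "byte"), id = NULL) {
  scale <- match.arg(scale)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  check_scale(pixels, scale)
  structure(list(pixels = pixels, scale = scale, id = id),
            class = "rgb_image")
}

#' Multispectral image container (green, red, red-edge, NIR)
#'
#' Holds an `H x W x 4` raster in the fixed band order green (550 nm),
#' red (660 nm), red-edge (735 nm), NIR (790 nm).
#'
#' @param pixels numeric `H x W x 4` array in the fixed band order.
#' @inheritParams rgb_image
#' @return an object of class `spectral_image`.
#' @export
spectral_image <- function(pixels, scale = c("unit", "byte"), id = NULL) {
  scale <- match.arg(scale)
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 4L)
    stop("`pixels` must be an H x W x 4 array (green, red, red_edge, nir)")
  check_scale(pixels, scale)
  structure(list(pixels = pixels, scale = scale, id = id,
                 band_centers_nm = VEGSR_BANDS,
                 band_names = names(VEGSR_BANDS)),
            class = "spectral_image")
}

#' Binary vegetation mask
#'
#' @param labels integer-like `H x W` matrix with values 0 (background) and
#'   1 (vegetation).
#' @param id optional sample identifier.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(labels, id = NULL) {
  labels <- as.matrix(labels)
  if (!all(labels %in% c(0, 1)))
    stop("mask labels must be 0 (background) or 1 (vegetation)")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, id = id), class = "binary_mask")
}

check_scale <- function(x, scale) {
  hi <- if (scale == "unit") 1 else 255
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > hi)
    stop(sprintf("pixel values outside declared %s scale [0, %s]", scale, hi))
  invisible(TRUE)
}

#' Convert an image to the unit scale [0, 1]
#'
#' @param img an `rgb_image` or `spectral_image`.
#' @return the same class of object on the unit scale.
#' @export
to_unit <- function(img) {
  if (img$scale == "unit") return(img)
  img$pixels <- img$pixels / 255
  img$scale <- "unit"
  img
}

#' Convert an image to the byte scale [0, 255]
#' @inheritParams to_unit
#' @return the same class of object on the byte scale.
#' @export
to_byte <- function(img) {
  if (img$scale == "byte") return(img)
  img$pixels <- img$pixels * 255
  img$scale <- "byte"
  img
}

# Pixels of an image-like object (array pass-through for convenience).
px <- function(img) {
  if (is.array(img)) img
  else if (inherits(img, c("rgb_image", "spectral_image"))) img$pixels
  else if (inherits(img, "binary_mask")) img$labels
  else if (inherits(img, "fused_map")) img$values
  else stop("unsupported image object")
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image %dx%d, %s scale%s>\n", d[1], d[2], x$scale,
              if (!is.null(x$id)) paste0(", id=", x$id) else ""))
  invisible(x)
}

#' @export
print.spectral_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<spectral_image %dx%d, bands %s, %s scale%s>\n", d[1], d[2],
              paste(x$band_names, collapse = "/"), x$scale,
              if (!is.null(x$id)) paste0(", id=", x$id) else ""))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<binary_mask %dx%d, %.1f%% vegetation>\n", d[1], d[2],
              100 * mean(x$labels)))
  invisible(x)
}
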