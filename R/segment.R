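# Thresholding a fused index map into a binary vegetation mask, with a
# fixed or adaptive (global-mean-based) threshold, plus the threshold
# sweep experiment.

#' Fixed-threshold segmentation
#'
#' Pixels strictly above `t` become vegetation (1); pixels at or below `t`
#' become background (0).  Equality is assigned to background — the
#' conservative class (the defining inequalities are strict on both sides
#' and leave equality open).
#'
#' @param map a `fused_map` (or plain matrix).
#' @param t threshold, on the map's scale.
#' @return a [binary_mask()].
#' @export
segment_fixed <- function(map, t) {
  binary_mask((px(map) > t) * 1L)
}

#' Adaptive threshold from the global mean of a weight-fused map
#'
#' Let `a = Avg(I_fw)` over the whole map (byte scale).  The threshold is
#' `phi_h * a` if `a > S_h`, `phi_l * a` if `a < S_l`, and `a` itself in
#' the middle band `S_l <= a <= S_h` (the neutral completion: the bright
#' and dark corrections are only defined outside the band).  Defaults are
#' the empirical setting `S_l = 145`, `S_h = 150`, `phi_l = 1.15`,
#' `phi_h = 0.9`.
#'
#' @param map a `fused_map` on the weight (byte) scale.
#' @param s_l,s_h lower and upper bound of the mean band (`s_l < s_h`).
#' @param phi_l,phi_h multiplicative corrections applied below/above the
#'   band.
#' @return the threshold, a scalar on the byte scale.
#' @export
adaptive_threshold <- function(map, s_l = 145, s_h = 150, phi_l = 1.15,
                               phi_h = 0.9) {
  stopifnot(s_l < s_h, phi_l > 0, phi_h > 0)
  v <- px(map)
  if (length(v) == 0) stop("empty map")
  a <- mean(v)
  if (a > s_h) phi_h * a else if (a < s_l) phi_l * a else a
}

#' Segment a fused index map into a vegetation mask
#'
#' Dispatches on the map's scale: vegetation-index maps get a fixed
#' threshold (default 0.2, the uniform comparison setting), weight-fused
#' maps get the adaptive global-mean threshold.  Both routes compose
#' [segment_fixed()] with the chosen threshold.
#'
#' @param map a `fused_map`.
#' @param mode `"fixed"` or `"adaptive"`; defaults by map scale
#'   (vi -> fixed, weight -> adaptive).
#' @param t fixed threshold (fixed mode).
#' @param ... passed to [adaptive_threshold()] in adaptive mode.
#' @return a [binary_mask()].
#' @export
segment <- function(map, mode = NULL, t = 0.2, ...) {
  stopifnot(inherits(map, "fused_map"))
  mode <- mode %||% switch(map$scale, vi = "fixed", weight = "adaptive",
                           stop("unknown map scale: ", map$scale))
  if (mode == "adaptive" && map$scale != "weight")
    stop("adaptive thresholding is defined on weight-scale maps")
  if (mode == "fixed" && map$scale == "vi" && abs(t) > 1)
    stop("fixed threshold ", t, " is outside the vi scale [-1, 1]")
  thr <- switch(mode,
                fixed = t,
                adaptive = adaptive_threshold(map, ...),
                stop("unknown mode: ", mode))
  segment_fixed(map, thr)
}

#' Threshold sweep: segmentation quality across a threshold grid
#'
#' Thresholds the map at every grid value and scores each mask against the
#' ground truth; the best threshold (highest MIoU, ties to the smallest
#' `t`) is attached as attribute `"best_t"`.
#'
#' @param map a `fused_map`.
#' @param gt ground-truth [binary_mask()].
#' @param grid numeric vector of thresholds (non-empty).
#' @return a data frame with columns `t`, `miou`, `pa`, `mpa`.
#' @export
sweep_thresholds <- function(map, gt, grid = seq(0, 0.4, by = 0.05)) {
  if (length(grid) == 0) stop("empty threshold grid")
  rows <- lapply(grid, function(t) {
    r <- confusion_miou(segment_fixed(map, t), gt)
    data.frame(t = t, miou = r$miou, pa = r$pa, mpa = r$mpa)
  })
  out <- do.call(rbind, rows)
  attr(out, "best_t") <- out$t[which.max(out$miou)]
  out
}
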