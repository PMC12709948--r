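# Reconstruction metrics (MSE, PSNR, SSIM, MRAE) and segmentation metrics
# (2x2 confusion, MIoU, PA, MPA).

as_pixels <- function(x) if (is.list(x)) px(x) else x

check_same_shape <- function(x, y) {
  if (!identical(dim(x) %||% length(x), dim(y) %||% length(y)))
    stop("inputs must have identical shape")
}

#' Mean squared error and peak signal-to-noise ratio
#'
#' `psnr()` returns `10 * log10(MAX^2 / MSE)` in dB, capped at `cap`
#' (identical inputs would otherwise be infinite).
#'
#' @param x,y numeric arrays of identical shape (or image objects).
#' @param max_value largest possible pixel value (1 for unit scale,
#'   255 for byte scale).
#' @param cap PSNR ceiling in dB.
#' @return a scalar.
#' @export
mse <- function(x, y) {
  x <- as_pixels(x); y <- as_pixels(y)
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' @rdname mse
#' @export
psnr <- function(x, y, max_value = 1, cap = 100) {
  m <- mse(x, y)
  if (m == 0) return(cap)
  min(10 * log10(max_value^2 / m), cap)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM over an 11x11 Gaussian window (sigma 1.5), computed on
#' the valid interior (no padding), with the usual stabilisers
#' `c1 = (0.01 MAX)^2`, `c2 = (0.03 MAX)^2`.  Single-band: multi-band
#' callers average over bands (see [recon_metrics()]).
#'
#' @param x,y numeric matrices of identical shape.
#' @param max_value largest possible pixel value.
#' @return a scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, max_value = 1) {
  ssim_stat(as_pixels(x), as_pixels(y), max_value)$value
}

ssim_window <- function() gauss_kernel_fixed(11L, 1.5)

gauss_kernel_fixed <- function(size, sigma) {
  r <- (size - 1L) %/% 2L
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# SSIM value plus everything needed for the analytic gradient.
ssim_stat <- function(x, y, max_value = 1) {
  check_same_shape(x, y)
  if (!is.matrix(x)) stop("ssim operates on single-band matrices")
  k <- ssim_window()
  r <- (length(k) - 1L) %/% 2L
  if (nrow(x) < length(k) || ncol(x) < length(k))
    stop("image smaller than the ", length(k), "x", length(k), " SSIM window")
  Mr <- conv_band_matrix(nrow(x), k, renormalize = FALSE)
  Mc <- conv_band_matrix(ncol(x), k, renormalize = FALSE)
  f <- function(z) Mr %*% z %*% t(Mc)
  ux <- f(x); uy <- f(y)
  vx <- f(x * x); vy <- f(y * y); vxy <- f(x * y)
  c1 <- (0.01 * max_value)^2; c2 <- (0.03 * max_value)^2
  A1 <- 2 * ux * uy + c1
  A2 <- 2 * (vxy - ux * uy) + c2
  B1 <- ux^2 + uy^2 + c1
  B2 <- (vx - ux^2) + (vy - uy^2) + c2
  S <- A1 * A2 / (B1 * B2)
  list(value = mean(S), S = S, ux = ux, uy = uy, B1 = B1, B2 = B2,
       A1 = A1, A2 = A2, Mr = Mr, Mc = Mc, x = x, y = y)
}

# d(mean SSIM)/dx via the chain rule through the windowed moments.
ssim_grad <- function(st) {
  with(st, {
    N <- length(S)
    dS_dux <- (2 * uy * A2 - 2 * uy * A1) / (B1 * B2) -
      S * (2 * ux / B1 - 2 * ux / B2)
    dS_dvx <- -S / B2
    dS_dvxy <- 2 * A1 / (B1 * B2)
    bt <- function(g) t(Mr) %*% g %*% Mc
    (bt(dS_dux) + 2 * x * bt(dS_dvx) + y * bt(dS_dvxy)) / N
  })
}

#' Mean relative absolute error (MRAE)
#'
#' `mean(|x - y| / max(y, eps))` with the reference `y` in the
#' denominator; the floor `eps = 1/255` (one 8-bit quantisation step on the
#' unit scale) guards against division by zero on dark pixels.
#'
#' @param x reconstructed data.
#' @param y reference data (denominator).
#' @param eps denominator floor.
#' @return a scalar >= 0.
#' @export
mrae <- function(x, y, eps = 1 / 255) {
  x <- as_pixels(x); y <- as_pixels(y)
  check_same_shape(x, y)
  mean(abs(x - y) / pmax(y, eps))
}

mrae_grad <- function(x, y, eps = 1 / 255) {
  sign(x - y) / pmax(y, eps) / length(x)
}

#' Reconstruction quality report (MRAE, SSIM, PSNR)
#'
#' SSIM is averaged over the four bands; PSNR uses the pooled MSE.
#'
#' @param recon,target [spectral_image()]s (or H x W x 4 arrays) on the
#'   unit scale.
#' @return a list with scalars `mrae`, `ssim`, `psnr` and 4-vectors
#'   `mrae_band`, `ssim_band`.
#' @export
recon_metrics <- function(recon, target) {
  xr <- as_pixels(recon); yt <- as_pixels(target)
  check_same_shape(xr, yt)
  sb <- vapply(seq_len(dim(xr)[3]),
               function(b) ssim(xr[, , b], yt[, , b]), numeric(1))
  mb <- vapply(seq_len(dim(xr)[3]),
               function(b) mrae(xr[, , b], yt[, , b]), numeric(1))
  list(mrae = mrae(xr, yt), ssim = mean(sb), psnr = psnr(xr, yt),
       mrae_band = mb, ssim_band = sb)
}

#' Composite reconstruction loss: MRAE + (1 - SSIM)
#'
#' The training objective: mean relative absolute error plus one minus the
#' band-averaged SSIM.  Zero iff the reconstruction equals the target.
#'
#' @inheritParams recon_metrics
#' @return a scalar.
#' @export
recon_loss <- function(recon, target) {
  m <- recon_metrics(recon, target)
  m$mrae + (1 - m$ssim)
}

#' Confusion table, MIoU, PA and MPA for a binary segmentation
#'
#' Per class c in \{background, vegetation\}:
#' `IoU_c = |P_c intersect G_c| / |P_c union G_c|`; MIoU is the mean of the
#' two class IoUs; PA is the fraction of pixels with `pred == gt`; MPA is
#' the mean per-class recall.  A class absent from both prediction and
#' ground truth contributes IoU 1 (vacuous agreement).  The confusion
#' table is normalised to percentages within each ground-truth class.
#'
#' @param pred,gt [binary_mask()]s or 0/1 matrices of identical shape.
#' @return a list of class `seg_report` with elements `confusion` (2x2,
#'   pred x gt, percent), `counts` (raw 2x2), `iou` (per class), `miou`,
#'   `pa`, `mpa`.
#' @export
confusion_miou <- function(pred, gt) {
  p <- as_pixels(pred); g <- as_pixels(gt)
  check_same_shape(p, g)
  counts <- matrix(c(sum(p == 0 & g == 0), sum(p == 1 & g == 0),
                     sum(p == 0 & g == 1), sum(p == 1 & g == 1)), 2, 2,
                   dimnames = list(pred = c("Back", "Veg"),
                                   gt = c("Back", "Veg")))
  iou_for <- function(tp, fp, fn) {
    denom <- tp + fp + fn
    if (denom == 0) 1 else tp / denom
  }
  iou <- c(Back = iou_for(counts[1, 1], counts[1, 2], counts[2, 1]),
           Veg = iou_for(counts[2, 2], counts[2, 1], counts[1, 2]))
  gt_tot <- colSums(counts)
  recall <- ifelse(gt_tot > 0, diag(counts) / gt_tot, 1)
  conf_pct <- sweep(counts, 2, pmax(gt_tot, 1), "/") * 100
  structure(list(confusion = conf_pct, counts = counts, iou = iou,
                 miou = mean(iou), pa = sum(diag(counts)) / sum(counts),
                 mpa = mean(recall)),
            class = "seg_report")
}

#' Aggregate segmentation reports over a test set
#'
#' The dataset MIoU/PA/MPA are the means of the per-image values (one term
#' per test image); pooled pixel counts and the per-class dataset-pooled
#' IoU are also reported for transparency.
#'
#' @param reports a list of `seg_report`s (from [confusion_miou()]).
#' @return a `seg_report` with extra fields `miou_pooled`, `n_images`.
#' @export
aggregate_seg <- function(reports) {
  stopifnot(length(reports) > 0)
  counts <- Reduce(`+`, lapply(reports, `[[`, "counts"))
  pooled <- confusion_miou(matrix(0, 1, 1), matrix(0, 1, 1)) # template
  pooled$counts <- counts
  gt_tot <- colSums(counts)
  pooled$confusion <- sweep(counts, 2, pmax(gt_tot, 1), "/") * 100
  iou_for <- function(tp, fp, fn) if (tp + fp + fn == 0) 1 else tp / (tp + fp + fn)
  pooled$iou <- c(Back = iou_for(counts[1, 1], counts[1, 2], counts[2, 1]),
                  Veg = iou_for(counts[2, 2], counts[2, 1], counts[1, 2]))
  pooled$miou_pooled <- mean(pooled$iou)
  pooled$miou <- mean(vapply(reports, `[[`, numeric(1), "miou"))
  pooled$pa <- mean(vapply(reports, `[[`, numeric(1), "pa"))
  pooled$mpa <- mean(vapply(reports, `[[`, numeric(1), "mpa"))
  pooled$n_images <- length(reports)
  pooled
}

#' @export
print.seg_report <- function(x, ...) {
  cat("Segmentation report")
  if (!is.null(x$n_images)) cat(sprintf(" (%d images)", x$n_images))
  cat("\nPred\\GT (%):\n")
  print(round(x$confusion, 1))
  cat(sprintf("MIoU %.3f | PA %.3f | MPA %.3f\n", x$miou, x$pa, x$mpa))
  invisible(x)
}
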