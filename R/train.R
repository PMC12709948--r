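# Training loop: Adam on random crops, composite MRAE + (1 - SSIM) loss,
# per-epoch metrics on a held-out evaluation set, optional downstream
# segmentation score per epoch.

# Normalise a sample (synthetic_sample or load_dataset() element) to
# list(x = HxWx3 array, y = HxWx4 array or NULL, mask = matrix or NULL).
sample_xy <- function(s) {
  tgt <- s$spectral %||% s$spectral_noisy
  list(x = px(s$rgb),
       y = if (!is.null(tgt)) px(tgt) else NULL,
       mask = if (!is.null(s$mask)) px(s$mask) else NULL)
}

# Composite loss and its gradient on a batch held as (cs*cs*B) x 4.
batch_loss_grad <- function(y, t0, cs, B) {
  g <- mrae_grad(y, t0)
  lm <- mrae(y, t0)
  ya <- array(y, c(cs, cs, B, 4L))
  ta <- array(t0, c(cs, cs, B, 4L))
  gs <- array(0, c(cs, cs, B, 4L))
  sv <- 0
  for (b in seq_len(B)) for (k in 1:4) {
    st <- ssim_stat(ya[, , b, k], ta[, , b, k])
    sv <- sv + st$value
    gs[, , b, k] <- ssim_grad(st)
  }
  sv <- sv / (4 * B)
  # loss = mrae + (1 - mean ssim)  ->  d/dy = mrae_grad - ssim_grad / (4B)
  list(loss = lm + (1 - sv),
       grad = g - matrix(gs, cs * cs * B, 4L) / (4 * B))
}

#' Train a spectral-reconstruction model
#'
#' Minimises the composite loss `MRAE + (1 - SSIM)` by Adam on random
#' square crops (with random horizontal flips) of the training pairs.
#' After every epoch the loss and reconstruction metrics are recomputed on
#' up to `eval_max` held-out samples, and — when those samples carry
#' ground-truth masks — the downstream segmentation MIoU of the epoch's
#' model under the uniform evaluation setting (vegetation-index fusion of
#' NIR against green, fixed threshold `seg_threshold`).
#'
#' The run is fully determined by `seed` (crop draws, batch order).
#'
#' @param model an [sr_model()].
#' @param data list of training samples: `synthetic_sample`s or
#'   [load_dataset()] elements with paired spectra.
#' @param epochs number of epochs (>= 1).
#' @param batch_size crops per gradient step.
#' @param learning_rate Adam learning rate (cosine-decayed over epochs).
#' @param crop_size square crop side; must not exceed the training images.
#' @param seed integer seed.
#' @param eval_data held-out samples for per-epoch metrics (defaults to
#'   `data`).
#' @param eval_max cap on evaluation images per epoch.
#' @param eval_segmentation_every evaluate segmentation MIoU every this
#'   many epochs (`0` disables it).
#' @param seg_threshold fixed vegetation-index threshold used in the
#'   per-epoch segmentation evaluation.
#' @param verbose print one line per epoch.
#' @return an object of class `sr_fit`: the trained model, an epoch-wise
#'   `history` data frame (`epoch`, `loss`, `mrae`, `ssim`, `psnr`,
#'   `seg_miou`), and parameter snapshots at the best-loss and
#'   best-segmentation epochs.
#' @export
sr_train <- function(model, data, epochs = 20L, batch_size = 16L,
                     learning_rate = 2e-3, crop_size = 32L, seed = 1L,
                     eval_data = NULL, eval_max = 4L,
                     eval_segmentation_every = 1L, seg_threshold = 0.2,
                     verbose = FALSE) {
  stopifnot(inherits(model, "sr_model"), epochs >= 1L)
  ds <- lapply(data, sample_xy)
  ds <- Filter(function(s) !is.null(s$y), ds)
  if (length(ds) == 0L) stop("no training samples with paired spectra")
  dims <- vapply(ds, function(s) dim(s$x)[1:2], numeric(2))
  if (crop_size > min(dims)) stop("crop_size exceeds the smallest training image")
  cs <- as.integer(crop_size)
  ev <- lapply(eval_data %||% data, sample_xy)
  ev <- Filter(function(s) !is.null(s$y), ev)
  ev <- utils::head(ev, eval_max)

  params <- model$params
  state <- adam_init(unlist_grads(params))
  hist <- vector("list", epochs)
  best <- list(loss = list(value = Inf, epoch = NA_integer_, params = NULL),
               seg = list(value = -Inf, epoch = NA_integer_, params = NULL))
  n <- length(ds)
  with_seed(derive_seed(seed, "train"), {
    for (ep in seq_len(epochs)) {
      lr <- learning_rate * (0.02 + 0.98 * 0.5 *
                               (1 + cos(pi * (ep - 1) / max(1, epochs))))
      perm <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = batch_size)) {
        take <- perm[start:min(start + batch_size - 1L, n)]
        B <- length(take)
        xa <- array(0, c(cs, cs, B, 3L))
        ta <- array(0, c(cs, cs, B, 4L))
        for (bi in seq_along(take)) {
          s <- ds[[take[bi]]]
          d <- dim(s$x)
          i0 <- sample.int(d[1] - cs + 1L, 1L)
          j0 <- sample.int(d[2] - cs + 1L, 1L)
          xi <- s$x[i0:(i0 + cs - 1L), j0:(j0 + cs - 1L), , drop = FALSE]
          yi <- s$y[i0:(i0 + cs - 1L), j0:(j0 + cs - 1L), , drop = FALSE]
          if (stats::runif(1) < 0.5) { # horizontal flip
            xi <- xi[, cs:1, , drop = FALSE]
            yi <- yi[, cs:1, , drop = FALSE]
          }
          xa[, , bi, ] <- xi
          ta[, , bi, ] <- yi
        }
        model$params <- params
        fwd <- model_forward(model, matrix(xa, cs * cs * B, 3L), cs, cs, B,
                             training = TRUE)
        lg <- batch_loss_grad(fwd$y, matrix(ta, cs * cs * B, 4L), cs, B)
        losses <- c(losses, lg$loss)
        grads <- model_backward(model, fwd$cache, lg$grad)
        # flatten W/b pairs for Adam
        flatg <- unlist_grads(grads)
        upd <- adam_step(unlist_grads(params), flatg, state, lr)
        state <- upd$state
        params <- relist_params(upd$params, params)
      }
      model$params <- params
      em <- eval_epoch(model, ev, ep, eval_segmentation_every, seg_threshold)
      hist[[ep]] <- data.frame(epoch = ep, loss = em$loss, mrae = em$mrae,
                               ssim = em$ssim, psnr = em$psnr,
                               seg_miou = em$seg_miou, train_loss = mean(losses),
                               lr = lr)
      if (em$loss < best$loss$value)
        best$loss <- list(value = em$loss, epoch = ep, params = params)
      if (!is.na(em$seg_miou) && em$seg_miou > best$seg$value)
        best$seg <- list(value = em$seg_miou, epoch = ep, params = params)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  mrae %.4f  ssim %.4f  psnr %5.1f  seg %.3f\n",
                    ep, em$loss, em$mrae, em$ssim, em$psnr, em$seg_miou))
    }
  })
  model$params <- params
  structure(list(model = model, history = do.call(rbind, hist), best = best,
                 config = list(epochs = epochs, batch_size = batch_size,
                               learning_rate = learning_rate,
                               crop_size = cs, seed = seed,
                               eval_segmentation_every = eval_segmentation_every,
                               seg_threshold = seg_threshold)),
            class = "sr_fit")
}

eval_epoch <- function(model, ev, epoch, seg_every, seg_threshold) {
  if (length(ev) == 0L)
    return(list(loss = NA_real_, mrae = NA_real_, ssim = NA_real_,
                psnr = NA_real_, seg_miou = NA_real_))
  do_seg <- seg_every > 0 && epoch %% seg_every == 0
  mr <- sv <- ps <- 0
  seg <- c()
  for (s in ev) {
    recon <- predict(model, s$x, clamp = TRUE)
    m <- recon_metrics(recon$pixels, s$y)
    mr <- mr + m$mrae; sv <- sv + m$ssim; ps <- ps + m$psnr
    if (do_seg && !is.null(s$mask)) {
      fused <- fuse_vi(recon)
      seg <- c(seg, confusion_miou(segment_fixed(fused, seg_threshold),
                                   s$mask)$miou)
    }
  }
  k <- length(ev)
  list(loss = mr / k + (1 - sv / k), mrae = mr / k, ssim = sv / k,
       psnr = ps / k,
       seg_miou = if (length(seg)) mean(seg) else NA_real_)
}

unlist_grads <- function(nested) {
  out <- list()
  for (nm in names(nested)) {
    out[[paste0(nm, ".W")]] <- nested[[nm]]$W
    out[[paste0(nm, ".b")]] <- nested[[nm]]$b
  }
  out
}

relist_params <- function(flat, template) {
  for (nm in names(template)) {
    template[[nm]]$W <- flat[[paste0(nm, ".W")]]
    template[[nm]]$b <- flat[[paste0(nm, ".b")]]
  }
  template
}

#' Select a checkpoint epoch from a training history
#'
#' `"reconstruction"` picks the epoch with the lowest evaluation loss;
#' `"segmentation"` picks the epoch with the highest downstream
#' segmentation MIoU.  Ties go to the earliest epoch.
#'
#' @param history an epoch-wise history data frame (or an `sr_fit`).
#' @param criterion `"reconstruction"` or `"segmentation"`.
#' @return the selected epoch (integer).
#' @export
select_checkpoint <- function(history,
                              criterion = c("reconstruction", "segmentation")) {
  criterion <- match.arg(criterion)
  if (inherits(history, "sr_fit")) history <- history$history
  if (nrow(history) == 0L) stop("empty history")
  if (criterion == "reconstruction") {
    v <- history$loss
    if (all(is.na(v))) stop("no loss records in history")
    history$epoch[which.min(v)] # which.min: first index on ties
  } else {
    v <- history$seg_miou
    if (all(is.na(v))) stop("no segmentation records in history")
    v[is.na(v)] <- -Inf
    history$epoch[which.max(v)]
  }
}

#' @export
print.sr_fit <- function(x, ...) {
  h <- x$history
  cat(sprintf("<sr_fit %s: %d epochs, final loss %.4f", x$model$variant,
              nrow(h), h$loss[nrow(h)]))
  if (!all(is.na(h$seg_miou)))
    cat(sprintf(", best seg MIoU %.3f (epoch %d)",
                max(h$seg_miou, na.rm = TRUE), x$best$seg$epoch))
  cat(">\n")
  invisible(x)
}

#' @export
summary.sr_fit <- function(object, ...) {
  print(object)
  print(utils::tail(object$history[, c("epoch", "loss", "mrae", "ssim",
                                       "psnr", "seg_miou")], 5))
  invisible(object$history)
}

#' Predict (reconstruct) from a fitted model
#'
#' @param object an `sr_fit`.
#' @param rgb RGB input, see [reconstruct()].
#' @param checkpoint which weights to use: the final epoch, the best-loss
#'   epoch, or the best-segmentation epoch.
#' @param clamp clamp output to `[0, 1]`.
#' @param ... unused.
#' @export
predict.sr_fit <- function(object, rgb,
                           checkpoint = c("final", "best_seg", "best_loss"),
                           clamp = TRUE, ...) {
  checkpoint <- match.arg(checkpoint)
  m <- object$model
  if (checkpoint == "best_loss" && !is.null(object$best$loss$params))
    m$params <- object$best$loss$params
  if (checkpoint == "best_seg" && !is.null(object$best$seg$params))
    m$params <- object$best$seg$params
  predict(m, rgb, clamp = clamp)
}

#' @export
plot.sr_fit <- function(x, ...) {
  h <- x$history
  has_seg <- !all(is.na(h$seg_miou))
  op <- graphics::par(mfrow = c(1, if (has_seg) 2 else 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch",
                 ylab = "MRAE + (1 - SSIM)", main = "reconstruction loss", ...)
  if (has_seg)
    graphics::plot(h$epoch, h$seg_miou, type = "b", xlab = "epoch",
                   ylab = "MIoU", main = "downstream segmentation", ...)
  invisible(x)
}

#' Save / load model weights
#'
#' The checkpoint is a JSON sidecar (config) plus an RDS weights file.
#'
#' @param model an `sr_model` or `sr_fit`.
#' @param path basename for the checkpoint files.
#' @export
save_checkpoint <- function(model, path) {
  if (inherits(model, "sr_fit")) model <- model$model
  jsonlite::write_json(list(variant = model$variant, width = model$width,
                            depth = model$depth, heads = model$heads),
                       paste0(path, ".json"), auto_unbox = TRUE)
  saveRDS(model$params, paste0(path, ".rds"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- sr_model(cfg$variant, cfg$width, cfg$depth, cfg$heads)
  m$params <- readRDS(paste0(path, ".rds"))
  m
}
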