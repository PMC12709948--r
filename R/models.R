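# The two RGB -> multispectral reconstruction models.
#
# SRCNet: a concatenation-heavy convolutional network.  Each block expands
# the running features with a 3x3 convolution (growth = 3 x width), ReLU,
# concatenates the block input back on (dense-style growth, so early
# features are carried forward intact), and fuses back to `width` channels
# with a 1x1 convolution.  No global residual path.
#
# SRANet: a spectral (channel-wise) self-attention network.  Each block
# applies multi-less attention where the tokens are the feature CHANNELS
# and the spatial positions act as the feature axis (the attention matrix
# is width x width, so its cost does not grow with image content
# ordering), with a residual connection, followed by a convolutional
# feed-forward sublayer (3x3 -> GELU -> 3x3) with a second residual.

#' Build a spectral-reconstruction model
#'
#' Constructs an untrained image-to-image operator mapping an RGB raster
#' (H x W x 3, unit scale) to a 4-band multispectral raster (H x W x 4).
#' Defaults are sized to the ~0.30 M (srcnet) and ~0.03 M (sranet)
#' trainable-parameter budgets of the two reference designs.
#'
#' @param variant `"srcnet"` (convolutional) or `"sranet"` (spectral
#'   self-attention).
#' @param width base feature count (default 32 for srcnet, 16 for sranet).
#' @param depth number of blocks (default 6 for srcnet, 3 for sranet).
#' @param heads attention heads (sranet only; heads partition the feature
#'   channels).
#' @param seed seed for the weight initialisation.
#' @param param_budget optional target parameter count; the built model
#'   must land within +/- 50 percent of it or construction fails.
#' @return an object of class `sr_model`.
#' @examples
#' m <- sr_model("sranet", seed = 1)
#' count_parameters(m)
#' @export
sr_model <- function(variant = c("srcnet", "sranet"), width = NULL,
                     depth = NULL, heads = 1L, seed = 1L,
                     param_budget = NULL) {
  variant <- match.arg(variant)
  width <- as.integer(width %||% if (variant == "srcnet") 32L else 16L)
  depth <- as.integer(depth %||% if (variant == "srcnet") 6L else 3L)
  stopifnot(width >= 4L, depth >= 1L, heads >= 1L)
  params <- with_seed(seed, {
    p <- list()
    w <- width
    p[["stem"]] <- nn_init(9L * 3L, w)
    if (variant == "srcnet") {
      g <- 3L * w
      for (i in seq_len(depth)) {
        p[[sprintf("b%d.conv", i)]] <- nn_init(9L * w, g)
        p[[sprintf("b%d.fuse", i)]] <- nn_init(w + g, w)
      }
    } else {
      for (i in seq_len(depth)) {
        for (nm in c("q", "k", "v"))
          p[[sprintf("b%d.%s", i, nm)]] <- nn_init(w, w)
        # residual branches start near identity
        p[[sprintf("b%d.o", i)]] <- nn_init(w, w, gain = 0.1)
        p[[sprintf("b%d.ffn1", i)]] <- nn_init(9L * w, 2L * w)
        p[[sprintf("b%d.ffn2", i)]] <- nn_init(9L * 2L * w, w, gain = 0.1)
      }
    }
    p[["head"]] <- nn_init(9L * w, 4L,
                           gain = if (variant == "sranet") 0.2 else 1)
    p
  })
  m <- structure(list(variant = variant, width = width, depth = depth,
                      heads = as.integer(heads), params = params),
                 class = "sr_model")
  if (!is.null(param_budget)) {
    n <- count_parameters(m)
    if (n < 0.5 * param_budget || n > 1.5 * param_budget)
      stop(sprintf("model has %d parameters, outside +/-50%% of the %d budget",
                   n, as.integer(param_budget)))
  }
  m
}

#' Number of trainable parameters of a model
#'
#' @param model an `sr_model` (or an `sr_fit`).
#' @return integer count of trainable scalars.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "sr_fit")) model <- model$model
  sum(vapply(model$params, function(p) length(p$W) + length(p$b), numeric(1)))
}

#' @export
print.sr_model <- function(x, ...) {
  cat(sprintf("<sr_model %s: width %d, depth %d%s, %s parameters>\n",
              x$variant, x$width, x$depth,
              if (x$variant == "sranet") paste0(", heads ", x$heads) else "",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- forward / backward -------------------------------------------------

model_forward <- function(model, x0, H, W, B, training = FALSE) {
  if (model$variant == "srcnet") srcnet_forward(model, x0, H, W, B, training)
  else sranet_forward(model, x0, H, W, B, training)
}

model_backward <- function(model, cache, dy) {
  if (model$variant == "srcnet") srcnet_backward(model, cache, dy)
  else sranet_backward(model, cache, dy)
}

srcnet_forward <- function(model, x0, H, W, B, training = FALSE) {
  p <- model$params
  cache <- if (training) list(H = H, W = W, B = B) else NULL
  cols0 <- nn_im2col(x0, H, W, B)
  s <- nn_affine(cols0, p$stem)
  x <- nn_relu(s)
  if (training) { cache$cols0 <- cols0; cache$s <- s }
  blk <- vector("list", model$depth)
  for (i in seq_len(model$depth)) {
    cols <- nn_im2col(x, H, W, B)
    hpre <- nn_affine(cols, p[[sprintf("b%d.conv", i)]])
    h <- nn_relu(hpre)
    cat_ <- cbind(x, h)
    xn <- nn_affine(cat_, p[[sprintf("b%d.fuse", i)]])
    if (training) blk[[i]] <- list(cols = cols, hpre = hpre, h = h,
                                   cat = cat_, xin = x)
    x <- xn
  }
  colsh <- nn_im2col(x, H, W, B)
  y <- nn_affine(colsh, p$head)
  if (training) { cache$blk <- blk; cache$colsh <- colsh }
  list(y = y, cache = cache)
}

srcnet_backward <- function(model, cache, dy) {
  p <- model$params
  H <- cache$H; W <- cache$W; B <- cache$B
  w <- model$width
  gr <- list()
  gr$head <- list(W = crossprod(cache$colsh, dy), b = colSums(dy))
  dx <- nn_col2im(dy %*% t(p$head$W), H, W, B, w)
  for (i in rev(seq_len(model$depth))) {
    cc <- cache$blk[[i]]
    fnm <- sprintf("b%d.fuse", i); cnm <- sprintf("b%d.conv", i)
    gr[[fnm]] <- list(W = crossprod(cc$cat, dx), b = colSums(dx))
    dcat <- dx %*% t(p[[fnm]]$W)
    dh <- dcat[, (w + 1L):ncol(dcat), drop = FALSE] * (cc$hpre > 0)
    gr[[cnm]] <- list(W = crossprod(cc$cols, dh), b = colSums(dh))
    dx <- dcat[, seq_len(w), drop = FALSE] +
      nn_col2im(dh %*% t(p[[cnm]]$W), H, W, B, w)
  }
  ds <- dx * (cache$s > 0)
  gr$stem <- list(W = crossprod(cache$cols0, ds), b = colSums(ds))
  gr[names(model$params)]
}

sranet_forward <- function(model, x0, H, W, B, training = FALSE) {
  p <- model$params
  n <- H * W
  cache <- if (training) list(H = H, W = W, B = B) else NULL
  cols0 <- nn_im2col(x0, H, W, B)
  s <- nn_affine(cols0, p$stem)
  x <- nn_gelu(s)
  if (training) { cache$cols0 <- cols0; cache$s <- s }
  blk <- vector("list", model$depth)
  for (i in seq_len(model$depth)) {
    Q <- nn_affine(x, p[[sprintf("b%d.q", i)]])
    K <- nn_affine(x, p[[sprintf("b%d.k", i)]])
    V <- nn_affine(x, p[[sprintf("b%d.v", i)]])
    O <- matrix(0, nrow(x), ncol(x))
    attn <- vector("list", B)
    hidx <- head_channel_chunks(model$width, model$heads)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * n + 1L):(b * n)
      attn[[b]] <- vector("list", length(hidx))
      for (h in seq_along(hidx)) {
        ch <- hidx[[h]]
        A <- nn_softmax_rows(crossprod(Q[rows, ch, drop = FALSE],
                                       K[rows, ch, drop = FALSE]) / sqrt(n))
        O[rows, ch] <- V[rows, ch, drop = FALSE] %*% t(A)
        if (training) attn[[b]][[h]] <- A
      }
    }
    x2 <- x + nn_affine(O, p[[sprintf("b%d.o", i)]])
    cols1 <- nn_im2col(x2, H, W, B)
    hpre <- nn_affine(cols1, p[[sprintf("b%d.ffn1", i)]])
    g <- nn_gelu(hpre)
    cols2 <- nn_im2col(g, H, W, B)
    x3 <- x2 + nn_affine(cols2, p[[sprintf("b%d.ffn2", i)]])
    if (training) blk[[i]] <- list(xin = x, Q = Q, K = K, V = V, O = O,
                                   attn = attn, x2 = x2, cols1 = cols1,
                                   hpre = hpre, cols2 = cols2)
    x <- x3
  }
  colsh <- nn_im2col(x, H, W, B)
  y <- nn_affine(colsh, p$head)
  if (training) { cache$blk <- blk; cache$colsh <- colsh }
  list(y = y, cache = cache)
}

sranet_backward <- function(model, cache, dy) {
  p <- model$params
  H <- cache$H; W <- cache$W; B <- cache$B
  n <- H * W
  w <- model$width
  gr <- list()
  gr$head <- list(W = crossprod(cache$colsh, dy), b = colSums(dy))
  dx <- nn_col2im(dy %*% t(p$head$W), H, W, B, w)
  for (i in rev(seq_len(model$depth))) {
    cc <- cache$blk[[i]]
    f2 <- sprintf("b%d.ffn2", i); f1 <- sprintf("b%d.ffn1", i)
    qn <- sprintf("b%d.q", i); kn <- sprintf("b%d.k", i)
    vn <- sprintf("b%d.v", i); on <- sprintf("b%d.o", i)
    # feed-forward sublayer (residual)
    gr[[f2]] <- list(W = crossprod(cc$cols2, dx), b = colSums(dx))
    dg <- nn_col2im(dx %*% t(p[[f2]]$W), H, W, B, 2L * w)
    dh <- dg * nn_gelu_grad(cc$hpre)
    gr[[f1]] <- list(W = crossprod(cc$cols1, dh), b = colSums(dh))
    dx2 <- dx + nn_col2im(dh %*% t(p[[f1]]$W), H, W, B, w)
    # attention sublayer (residual)
    dO <- dx2 %*% t(p[[on]]$W)
    gr[[on]] <- list(W = crossprod(cc$O, dx2), b = colSums(dx2))
    dQ <- matrix(0, nrow(dx2), w); dK <- dQ; dV <- dQ
    hidx <- head_channel_chunks(model$width, model$heads)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * n + 1L):(b * n)
      for (h in seq_along(hidx)) {
        ch <- hidx[[h]]
        A <- cc$attn[[b]][[h]]
        dOb <- dO[rows, ch, drop = FALSE]
        Vb <- cc$V[rows, ch, drop = FALSE]
        dV[rows, ch] <- dOb %*% A
        dA <- t(crossprod(Vb, dOb))      # dL/dA
        dS <- A * (dA - rowSums(dA * A)) # softmax rows backward
        dQ[rows, ch] <- cc$K[rows, ch, drop = FALSE] %*% t(dS) / sqrt(n)
        dK[rows, ch] <- cc$Q[rows, ch, drop = FALSE] %*% dS / sqrt(n)
      }
    }
    gr[[qn]] <- list(W = crossprod(cc$xin, dQ), b = colSums(dQ))
    gr[[kn]] <- list(W = crossprod(cc$xin, dK), b = colSums(dK))
    gr[[vn]] <- list(W = crossprod(cc$xin, dV), b = colSums(dV))
    dx <- dx2 + dQ %*% t(p[[qn]]$W) + dK %*% t(p[[kn]]$W) +
      dV %*% t(p[[vn]]$W)
  }
  ds <- dx * nn_gelu_grad(cache$s)
  gr$stem <- list(W = crossprod(cache$cols0, ds), b = colSums(ds))
  gr[names(model$params)]
}

# Channel index chunks for multi-head spectral attention (tokens are
# channels; heads partition the channel set).
head_channel_chunks <- function(width, heads) {
  stopifnot(width %% heads == 0)
  per <- width %/% heads
  lapply(seq_len(heads), function(h) ((h - 1L) * per + 1L):(h * per))
}

# --- inference ----------------------------------------------------------

#' Reconstruct a 4-band multispectral image from RGB
#'
#' Applies a (trained or untrained) model to an RGB image of any size
#' >= 8 px per side.  The output is clamped to the unit interval at
#' inference.
#'
#' @param model an `sr_model` or `sr_fit`.
#' @param rgb an [rgb_image()] (unit scale) or H x W x 3 array.
#' @param clamp clamp the output to `[0, 1]` (default `TRUE`); with
#'   `clamp = FALSE` the raw head output is returned as a plain array
#'   (useful for diagnostics; it can fall outside the unit scale).
#' @return a [spectral_image()] (or a plain array when `clamp = FALSE`).
#' @export
reconstruct <- function(model, rgb, clamp = TRUE) {
  if (inherits(model, "sr_fit")) return(predict(model, rgb, clamp = clamp))
  predict(model, rgb, clamp = clamp)
}

#' @rdname reconstruct
#' @param object an `sr_model`.
#' @param ... unused.
#' @export
predict.sr_model <- function(object, rgb, clamp = TRUE, ...) {
  if (inherits(rgb, "rgb_image")) {
    if (rgb$scale != "unit")
      stop("reconstruction expects unit-scale input; see to_unit()")
    a <- rgb$pixels
  } else a <- rgb
  d <- dim(a)
  if (length(d) != 3L || d[3] != 3L) stop("expected an H x W x 3 RGB raster")
  if (d[1] < 8L || d[2] < 8L) stop("image must be at least 8 x 8")
  x0 <- matrix(a, d[1] * d[2], 3L)
  y <- model_forward(object, x0, d[1], d[2], 1L, training = FALSE)$y
  if (!clamp) return(array(y, c(d[1], d[2], 4L))) # raw output, diagnostics
  spectral_image(array(clip01(y), c(d[1], d[2], 4L)),
                 id = if (inherits(rgb, "rgb_image")) rgb$id else NULL)
}
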