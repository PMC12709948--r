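# Minimal neural-network engine: feature maps are (H*W*B) x C matrices
# (rows ordered pixel-column-major within image, then image), 3x3
# convolutions go through im2col + BLAS matrix products with replicate
# padding, and gradients are hand-derived per layer.  Kept in base R: the
# heavy lifting is dgemm either way.

# Expand x into the 3x3 neighbourhood matrix: (H*W*B) x (9*C), column
# blocks ordered by kernel offset (column-major over the 3x3 stencil),
# channels fastest within a block.  Replicate padding at the borders.
nn_im2col <- function(x, H, W, B) {
  C <- ncol(x)
  a <- array(x, c(H, W, B, C))
  ap <- array(0, c(H + 2L, W + 2L, B, C))
  ap[2:(H + 1), 2:(W + 1), , ] <- a
  ap[1, 2:(W + 1), , ] <- a[1, , , ]
  ap[H + 2, 2:(W + 1), , ] <- a[H, , , ]
  ap[, 1, , ] <- ap[, 2, , ]
  ap[, W + 2, , ] <- ap[, W + 1, , ]
  out <- matrix(0, H * W * B, 9L * C)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    out[, ((k - 1L) * C + 1L):(k * C)] <- ap[(1 + di):(H + di), (1 + dj):(W + dj), , ]
  }
  out
}

# Adjoint of nn_im2col (scatter-add, folding the replicate padding back
# onto the edge pixels).
nn_col2im <- function(dcols, H, W, B, C) {
  gp <- array(0, c(H + 2L, W + 2L, B, C))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    gp[(1 + di):(H + di), (1 + dj):(W + dj), , ] <-
      gp[(1 + di):(H + di), (1 + dj):(W + dj), , , drop = FALSE] +
      array(dcols[, ((k - 1L) * C + 1L):(k * C)], c(H, W, B, C))
  }
  gp[, 2, , ] <- gp[, 2, , ] + gp[, 1, , ]
  gp[, W + 1, , ] <- gp[, W + 1, , ] + gp[, W + 2, , ]
  gp[2, 2:(W + 1), , ] <- gp[2, 2:(W + 1), , ] + gp[1, 2:(W + 1), , ]
  gp[H + 1, 2:(W + 1), , ] <- gp[H + 1, 2:(W + 1), , ] + gp[H + 2, 2:(W + 1), , ]
  matrix(gp[2:(H + 1), 2:(W + 1), , ], H * W * B, C)
}

nn_relu <- function(x) pmax(x, 0)
nn_gelu <- function(x) x * stats::pnorm(x)
nn_gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# He-normal initialised conv/linear weight (fan_in x fan_out) + zero bias.
# `gain` < 1 tempers residual-branch outputs (near-identity start).
nn_init <- function(fan_in, fan_out, gain = 1) {
  list(W = matrix(stats::rnorm(fan_in * fan_out, 0, gain * sqrt(2 / fan_in)),
                  fan_in, fan_out),
       b = numeric(fan_out))
}

nn_affine <- function(x, p) sweep(x %*% p$W, 2, p$b, `+`)

# Row-wise softmax of a small matrix.
nn_softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1, max))
  e / rowSums(e)
}

# --- Adam ---------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}
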