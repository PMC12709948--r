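test_that("both variants honour the spatial shape contract", {
  for (v in c("srcnet", "sranet")) {
    m <- sr_model(v, width = 8, depth = 2, seed = 1)
    out <- predict(m, rand_raster(16, 16, 3, seed = 2))
    expect_identical(dim(out$pixels), c(16L, 16L, 4L))
    odd <- predict(m, rand_raster(37, 41, 3, seed = 3))
    expect_identical(dim(odd$pixels), c(37L, 41L, 4L))
  }
  expect_error(predict(sr_model("srcnet", width = 8, depth = 1),
                       rand_raster(4, 4, 3)), "at least 8")
})

test_that("reconstruction is deterministic, clamped, and size-independent", {
  m <- sr_model("srcnet", width = 8, depth = 2, seed = 7)
  a <- rand_raster(16, 16, 3, seed = 4)
  expect_identical(predict(m, a)$pixels, predict(m, a)$pixels)
  y <- predict(m, a)$pixels
  expect_true(all(y >= 0 & y <= 1))
  n0 <- count_parameters(m)
  invisible(predict(m, rand_raster(24, 24, 3, seed = 5)))
  expect_identical(count_parameters(m), n0)
  expect_error(predict(m, to_byte(rgb_image(a))), "unit-scale")
})

test_that("parameter counts match hand arithmetic and the design budgets", {
  # a single 3x3 convolution, 3 -> 4 channels, with bias: 3*4*9 + 4
  p <- vegsr:::nn_init(9 * 3, 4)
  expect_identical(length(p$W) + length(p$b), 112L)

  expect_identical(count_parameters(sr_model("srcnet")), 193284)
  expect_identical(count_parameters(sr_model("sranet")), 32084)
  # budgets: ~0.30 M and ~0.03 M designs within +/- 50%
  expect_true(count_parameters(sr_model("srcnet")) %in% 150000:450000)
  expect_true(count_parameters(sr_model("sranet")) %in% 15000:45000)

  # degenerate depth-1 srcnet: stem + one block + head, by hand
  m1 <- sr_model("srcnet", width = 8, depth = 1)
  stem <- 27 * 8 + 8; conv <- 72 * 24 + 24; fuse <- 32 * 8 + 8
  head <- 72 * 4 + 4
  expect_identical(count_parameters(m1), stem + conv + fuse + head)
})

test_that("an explicit parameter budget is enforced within +/-50%", {
  expect_s3_class(sr_model("srcnet", param_budget = 3e5), "sr_model")
  expect_error(sr_model("srcnet", param_budget = 3e6), "outside")
  expect_error(sr_model("sranet", param_budget = 1e3), "outside")
})

test_that("spectral attention rows are a probability distribution", {
  m <- sr_model("sranet", width = 8, depth = 1, seed = 9)
  x0 <- matrix(runif(12 * 12 * 3), 12 * 12, 3)
  fwd <- vegsr:::model_forward(m, x0, 12L, 12L, 1L, training = TRUE)
  A <- fwd$cache$blk[[1]]$attn[[1]][[1]]
  expect_equal(unname(rowSums(A)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(A >= 0))
})

test_that("analytic gradients agree with finite differences", {
  set.seed(10)
  for (v in c("srcnet", "sranet")) {
    m <- sr_model(v, width = 8, depth = 1, seed = 11)
    H <- W <- 9L
    x0 <- matrix(runif(H * W * 3), H * W, 3)
    fwd <- vegsr:::model_forward(m, x0, H, W, 1L, training = TRUE)
    gr <- vegsr:::model_backward(m, fwd$cache, fwd$y) # loss = sum(y^2)/2
    lossfn <- function(params) {
      m2 <- m; m2$params <- params
      sum(vegsr:::model_forward(m2, x0, H, W, 1L)$y^2) / 2
    }
    for (nm in names(m$params)) {
      k <- sample(length(m$params[[nm]]$W), 1)
      p2 <- m$params; p2[[nm]]$W[k] <- p2[[nm]]$W[k] + 1e-5
      p3 <- m$params; p3[[nm]]$W[k] <- p3[[nm]]$W[k] - 1e-5
      num <- (lossfn(p2) - lossfn(p3)) / 2e-5
      expect_equal(gr[[nm]]$W[k], num, tolerance = 1e-4)
    }
  }
})

test_that("reconstruction commutes with translation away from borders", {
  set.seed(12)
  a <- rand_raster(28, 28, 3)
  shift <- 4L
  a_sh <- a[(1 + shift):28, (1 + shift):28, , drop = FALSE]
  inner <- 9:16

  m <- sr_model("srcnet", width = 8, depth = 2, seed = 13)
  y <- predict(m, a)$pixels
  y_sh <- predict(m, a_sh)$pixels
  expect_equal(y[inner + shift, inner + shift, ], y_sh[inner, inner, ],
               tolerance = 1e-10)

  # attention pools globally, so equivariance is only approximate
  ma <- sr_model("sranet", width = 8, depth = 1, seed = 14)
  ya <- predict(ma, a)$pixels
  ya_sh <- predict(ma, a_sh)$pixels
  expect_equal(ya[inner + shift, inner + shift, ], ya_sh[inner, inner, ],
               tolerance = 0.05)
})

test_that("checkpoints round-trip through disk", {
  d <- withr::local_tempdir()
  m <- sr_model("sranet", width = 8, depth = 1, seed = 15)
  save_checkpoint(m, file.path(d, "ck"))
  m2 <- load_checkpoint(file.path(d, "ck"))
  a <- rand_raster(12, 12, 3, seed = 16)
  expect_identical(predict(m2, a)$pixels, predict(m, a)$pixels)
})
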