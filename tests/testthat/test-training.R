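tiny_scenes <- function(n, seed, size = 24L, noise = 0.01) {
  simulate_scenes(n, list(height = size, width = size,
                          pixel_noise_sd = noise,
                          target_veg_fraction = c(0.2, 0.4)), seed = seed)
}

test_that("the composite loss decomposes into MRAE and 1 - SSIM", {
  set.seed(1)
  x <- rand_raster(16, 16, 4); y <- rand_raster(16, 16, 4)
  m <- recon_metrics(x, y)
  expect_equal(recon_loss(x, y), m$mrae + (1 - m$ssim), tolerance = 1e-12)
  expect_identical(recon_loss(y, y), 0)
  expect_gte(recon_loss(x, y), 0)
  expect_error(recon_loss(rand_raster(16, 16, 4), rand_raster(16, 18, 4)),
               "shape")
})

test_that("training is reproducible and records one row per epoch", {
  scenes <- tiny_scenes(6, seed = 2)
  run <- function() sr_train(sr_model("srcnet", width = 8, depth = 1, seed = 3),
                             scenes[1:4], epochs = 2, batch_size = 2,
                             crop_size = 16, seed = 4,
                             eval_data = scenes[5:6])
  f1 <- run(); f2 <- run()
  expect_identical(f1$history, f2$history)
  expect_identical(nrow(f1$history), 2L)
  expect_identical(f1$model$params, f2$model$params)
  # the per-epoch loss decomposes exactly into its two metric terms
  expect_equal(f1$history$loss,
               f1$history$mrae + (1 - f1$history$ssim), tolerance = 1e-6)
})

test_that("training reduces the loss on clean synthetic data", {
  scenes <- tiny_scenes(8, seed = 5)
  fit <- sr_train(sr_model("srcnet", width = 8, depth = 2, seed = 6),
                  scenes[1:6], epochs = 8, batch_size = 4, crop_size = 16,
                  seed = 7, eval_data = scenes[7:8])
  h <- fit$history
  expect_lt(h$loss[nrow(h)], h$loss[1])
  expect_true(all(is.finite(h$loss)))
})

test_that("training refuses datasets without paired spectra", {
  scenes <- tiny_scenes(3, seed = 8)
  stripped <- lapply(scenes, function(s) list(rgb = s$rgb))
  expect_error(sr_train(sr_model("srcnet", width = 8, depth = 1), stripped,
                        epochs = 1), "paired spectra")
  expect_error(sr_train(sr_model("srcnet", width = 8, depth = 1), scenes,
                        epochs = 1, crop_size = 64), "crop_size")
})

test_that("both models can overfit a small noiseless set", {
  sigs <- lapply(default_signatures(), function(s) { s$jitter_sd <- 0; s })
  scenes <- simulate_scenes(4, list(height = 20L, width = 20L,
                                    pixel_noise_sd = 0,
                                    target_veg_fraction = c(0.2, 0.4)),
                            seed = 9, signatures = sigs)
  for (v in c("srcnet", "sranet")) {
    fit <- sr_train(sr_model(v, width = 16, depth = 2, seed = 10),
                    scenes, epochs = 150, batch_size = 2, crop_size = 16,
                    learning_rate = 4e-3, seed = 11, eval_data = scenes,
                    eval_segmentation_every = 0)
    expect_lt(min(fit$history$loss), 0.1)
  }
})

test_that("a model fits a single constant pair to near-zero MRAE", {
  x <- array(0.4, c(16, 16, 3))
  y <- array(rep(c(0.1, 0.2, 0.6, 0.7), each = 256), c(16, 16, 4))
  data <- list(list(rgb = rgb_image(x), spectral = spectral_image(y)))
  fit <- sr_train(sr_model("srcnet", width = 8, depth = 1, seed = 12),
                  data, epochs = 120, batch_size = 1, crop_size = 16,
                  seed = 13, eval_segmentation_every = 0)
  recon <- predict(fit, x)
  expect_lt(mrae(recon$pixels, y), 0.05)
})

test_that("checkpoint selection follows argmin/argmax with earliest ties", {
  h <- data.frame(epoch = 1:3, loss = c(0.5, 0.3, 0.4),
                  seg_miou = c(0.5, 0.8, 0.7))
  expect_identical(select_checkpoint(h, "reconstruction"), 2L)
  expect_identical(select_checkpoint(h, "segmentation"), 2L)
  ties <- data.frame(epoch = 1:3, loss = c(0.2, 0.2, 0.2),
                     seg_miou = c(0.6, 0.6, 0.6))
  expect_identical(select_checkpoint(ties, "reconstruction"), 1L)
  expect_identical(select_checkpoint(ties, "segmentation"), 1L)
  no_seg <- data.frame(epoch = 1:2, loss = c(0.4, 0.2),
                       seg_miou = c(NA_real_, NA_real_))
  expect_error(select_checkpoint(no_seg, "segmentation"), "no segmentation")
  expect_error(select_checkpoint(h[0, ], "reconstruction"), "empty")
})
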