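test_that("PSNR/MSE identities and the constant-offset value hold", {
  x <- rand_raster(8, 8, 1, seed = 1)[, , 1]
  expect_identical(mse(x, x), 0)
  expect_identical(psnr(x, x), 100)

  X <- matrix(0, 8, 8); Y <- matrix(10, 8, 8)
  expect_equal(mse(X, Y), 100)
  expect_equal(psnr(X, Y, max_value = 255), 10 * log10(255^2 / 100))
  expect_equal(round(psnr(X, Y, max_value = 255), 2), 28.13)

  expect_equal(mse(X + 5, Y + 5), mse(X, Y)) # translation invariance
  expect_error(mse(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
})

test_that("SSIM matches its closed forms and is symmetric", {
  x <- rand_raster(16, 16, 1, seed = 2)[, , 1]
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, 1 - x), ssim(1 - x, x))

  # constant images: variances vanish, S = (2ab+c1)/(a^2+b^2+c1)
  a <- 0.3; b <- 0.7
  expect_equal(ssim(matrix(a, 16, 16), matrix(b, 16, 16)),
               (2 * a * b + 1e-4) / (a^2 + b^2 + 1e-4), tolerance = 1e-12)
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "window")
})

test_that("MRAE hand values, asymmetry, and the denominator floor", {
  x <- rand_raster(6, 6, 1, seed = 3)[, , 1]
  expect_identical(mrae(x, x), 0)
  y <- x * 0 + 0.5
  expect_equal(mrae(1.2 * y, y), 0.2)
  expect_equal(mrae(c(0.6, 0.8), c(0.5, 1.0)), 0.2)
  expect_false(isTRUE(all.equal(mrae(c(0.2, 0.9), c(0.7, 0.4)),
                                mrae(c(0.7, 0.4), c(0.2, 0.9)))))
  # zero reference pixels hit the 1/255 floor instead of dividing by zero
  expect_equal(mrae(0.1, 0), 0.1 * 255)
})

test_that("all reconstruction metrics match per-pixel brute-force loops", {
  set.seed(4)
  for (k in 1:3) {
    x <- rand_raster(8, 8, 1)[, , 1]; y <- rand_raster(8, 8, 1)[, , 1]
    expect_equal(mse(x, y), oracle_mse(x, y), tolerance = 1e-9)
    expect_equal(psnr(x, y), oracle_psnr(x, y), tolerance = 1e-9)
    expect_equal(mrae(x, y), oracle_mrae(x, y), tolerance = 1e-9)
  }
  xs <- rand_raster(12, 12, 1)[, , 1]; ys <- rand_raster(12, 12, 1)[, , 1]
  expect_equal(ssim(xs, ys), oracle_ssim(xs, ys), tolerance = 1e-9)
})

test_that("the analytic SSIM gradient matches finite differences", {
  set.seed(44)
  x <- rand_raster(14, 14, 1)[, , 1]; y <- rand_raster(14, 14, 1)[, , 1]
  g <- vegsr:::ssim_grad(vegsr:::ssim_stat(x, y))
  h <- 1e-6
  for (idx in list(c(1, 1), c(7, 7), c(14, 3))) {
    xp <- x; xp[idx[1], idx[2]] <- xp[idx[1], idx[2]] + h
    xm <- x; xm[idx[1], idx[2]] <- xm[idx[1], idx[2]] - h
    num <- (ssim(xp, y) - ssim(xm, y)) / (2 * h)
    expect_equal(g[idx[1], idx[2]], num, tolerance = 1e-6)
  }
})

test_that("confusion table, MIoU, PA and MPA follow the set definitions", {
  gt <- binary_mask(matrix(c(1, 0, 1, 0), 2, 2))
  expect_equal(confusion_miou(gt, gt)$miou, 1)
  expect_equal(confusion_miou(gt, gt)$pa, 1)
  expect_equal(confusion_miou(gt, gt)$mpa, 1)

  # all-vegetation prediction against a half-vegetation truth
  allv <- binary_mask(matrix(1, 2, 2))
  r <- confusion_miou(allv, gt)
  expect_equal(unname(r$iou), c(0, 0.5))
  expect_equal(r$miou, 0.25)
  expect_equal(r$pa, 0.5)

  # symmetry of IoU under swapping prediction and truth
  p <- binary_mask(matrix(c(1, 1, 0, 0), 2, 2))
  expect_equal(confusion_miou(p, gt)$miou, confusion_miou(gt, p)$miou)

  # absent-class convention: both all-background -> vacuous agreement
  z <- binary_mask(matrix(0, 3, 3))
  expect_equal(confusion_miou(z, z)$miou, 1)

  # confusion columns are percentages within each ground-truth class
  expect_equal(unname(colSums(r$confusion)), c(100, 100))

  # brute-force cross-check on random masks; MIoU = 1 iff identical
  set.seed(5)
  for (k in 1:5) {
    pm <- matrix(rbinom(64, 1, 0.4), 8, 8)
    gm <- matrix(rbinom(64, 1, 0.4), 8, 8)
    expect_equal(confusion_miou(pm, gm)$miou, oracle_miou(pm, gm),
                 tolerance = 1e-9)
    if (!identical(pm, gm)) expect_lt(confusion_miou(pm, gm)$miou, 1)
  }
})

test_that("dataset aggregation averages per-image scores and pools counts", {
  r1 <- confusion_miou(matrix(1, 2, 2), matrix(c(1, 1, 0, 0), 2, 2))
  r2 <- confusion_miou(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 0, 0, 0), 2, 2))
  agg <- aggregate_seg(list(r1, r2))
  expect_equal(agg$miou, mean(c(r1$miou, r2$miou)))
  expect_equal(agg$n_images, 2L)
  expect_equal(sum(agg$counts), 8)
})
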