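test_that("RGB PNG round-trip preserves 8-bit data and zero images", {
  d <- withr::local_tempdir()
  z <- rgb_image(array(0, c(2, 2, 3)))
  p <- file.path(d, "z.png")
  write_rgb(z, p)
  back <- read_rgb(p)
  expect_equal(back$pixels, z$pixels)
  expect_identical(sum(back$pixels), 0)

  a <- rand_raster(15, 11, 3, quantize = TRUE, seed = 1)
  p2 <- file.path(d, "a.png")
  write_rgb(rgb_image(a), p2)
  expect_equal(read_rgb(p2)$pixels, a)
})

test_that("read_rgb rejects missing files and wrong channel counts", {
  expect_error(read_rgb("no/such/file.png"), "not found")
  d <- withr::local_tempdir()
  p <- file.path(d, "four.tif")
  tiff::writeTIFF(rand_raster(6, 6, 4, seed = 2), p)
  expect_error(suppressWarnings(read_rgb(p)), "3-channel")
})

test_that("spectral TIFF round-trip is lossless for 8-bit data", {
  d <- withr::local_tempdir()
  a <- rand_raster(13, 9, 4, quantize = TRUE, seed = 3)
  p <- file.path(d, "ms.tif")
  write_spectral(spectral_image(a), p)
  back <- read_spectral(p)
  expect_equal(back$pixels, a)
  expect_identical(back$band_names, c("green", "red", "red_edge", "nir"))

  # a freshly generated scene survives the trip at 8-bit precision
  s <- generate_scene(scene_spec(height = 16, width = 16, seed = 4))
  q <- round(s$spectral_clean$pixels * 255) / 255
  write_spectral(spectral_image(q), p)
  expect_equal(read_spectral(p)$pixels, q)
})

test_that("read_spectral rejects wrong page counts", {
  d <- withr::local_tempdir()
  p <- file.path(d, "three.tif")
  tiff::writeTIFF(lapply(1:3, function(i) matrix(0.5, 5, 5)), p)
  expect_error(read_spectral(p), "4-page")
})

test_that("mask PNG round-trip maps {0,1} <-> {0,255}", {
  d <- withr::local_tempdir()
  m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2))
  p <- file.path(d, "m.png")
  write_mask(m, p)
  expect_identical(read_mask(p)$labels, m$labels)
})

test_that("patch extraction matches the sensor geometry and brute force", {
  img <- rgb_image(array(0, c(1280, 960, 3)))
  expect_length(extract_patches(img, 340), 6L)

  # identity and degenerate cases
  one <- rgb_image(rand_raster(340, 340, 3, seed = 5))
  ps <- extract_patches(one, 340)
  expect_length(ps, 1L)
  expect_equal(ps[[1]]$pixels, one$pixels)
  expect_length(extract_patches(rgb_image(rand_raster(339, 339, 3)), 340), 0L)

  # property: count = floor(H/p) * floor(W/p) against the enumeration oracle
  set.seed(6)
  for (k in 1:10) {
    H <- sample(1:40, 1); W <- sample(1:40, 1); p <- sample(1:15, 1)
    got <- length(extract_patches(matrix(0, H, W), p))
    expect_identical(got, oracle_patch_count(H, W, p))
    expect_identical(got, length(extract_patches(array(0, c(H, W, 3)), p)))
    expect_identical(got, (H %/% p) * (W %/% p))
  }

  # patches are in row-major order and tile the image content
  m <- matrix(1:36, 6, 6)
  tiles <- extract_patches(m, 3)
  expect_equal(tiles[[1]], m[1:3, 1:3])
  expect_equal(tiles[[2]], m[1:3, 4:6])
  expect_equal(tiles[[4]], m[4:6, 4:6])
})

test_that("dataset split is an exact, reproducible partition", {
  m <- manifest(id = sprintf("s%02d", 1:20), rgb = sprintf("r%02d.png", 1:20))
  s1 <- split_dataset(m, 0.9, seed = 7)
  expect_identical(sum(s1$split == "train"), 18L)
  expect_identical(sum(s1$split == "test"), 2L)
  s2 <- split_dataset(m, 0.9, seed = 7)
  expect_identical(s1$split, s2$split)
  expect_false(identical(s1$split, split_dataset(m, 0.9, seed = 8)$split))
  expect_error(split_dataset(m, 1.0, seed = 1), "inside")
  expect_error(split_dataset(m[0, ], 0.9, seed = 1), "empty")
  # partition property across random n and ratios
  set.seed(8)
  for (k in 1:5) {
    n <- sample(5:50, 1)
    r <- runif(1, 0.2, 0.8)
    mm <- split_dataset(manifest(seq_len(n), "x"), r, seed = k)
    expect_identical(sum(mm$split == "train"), as.integer(round(r * n)))
    expect_true(all(mm$split %in% c("train", "test")))
  }
})
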