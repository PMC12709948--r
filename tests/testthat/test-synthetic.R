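test_that("scene generation is seeded, calibrated, and honours zero fractions", {
  s0 <- generate_scene(scene_spec(target_veg_fraction = 0, seed = 1))
  expect_identical(sum(s0$mask$labels), 0L)

  a <- generate_scene(scene_spec(seed = 42))
  b <- generate_scene(scene_spec(seed = 42))
  expect_identical(a$rgb$pixels, b$rgb$pixels)
  expect_identical(a$spectral_clean$pixels, b$spectral_clean$pixels)
  expect_identical(a$mask$labels, b$mask$labels)

  # quantile calibration keeps the realised fraction on target
  fr <- vapply(simulate_scenes(100, list(target_veg_fraction = 0.3), seed = 5),
               function(s) mean(s$mask$labels), numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 0.05)
})

test_that("every layout renders both classes at the requested fraction", {
  for (lay in c("dense", "row_crop", "mixed")) {
    s <- generate_scene(scene_spec(layout = lay, target_veg_fraction = 0.4,
                                   seed = 9))
    expect_lt(abs(mean(s$mask$labels) - 0.4), 0.05)
  }
})

test_that("vegetation/background NDVI contrast meets the construction margin", {
  scenes <- simulate_scenes(10, list(target_veg_fraction = c(0.2, 0.4)),
                            seed = 11)
  margins <- vapply(scenes, function(s) {
    v <- fuse_vi(s$spectral_clean)$values
    veg <- s$mask$labels == 1
    mean(v[veg]) - mean(v[!veg])
  }, numeric(1))
  expect_true(all(margins >= 0.3))
})

test_that("index thresholded at zero recovers the generator mask on quiet scenes", {
  scenes <- simulate_scenes(10, list(pixel_noise_sd = 0.02,
                                     target_veg_fraction = c(0.2, 0.4)),
                            seed = 13)
  mious <- vapply(scenes, function(s)
    confusion_miou(segment_fixed(fuse_vi(s$spectral_clean), 0),
                   s$mask)$miou, numeric(1))
  expect_gte(mean(mious), 0.95)
})

test_that("strong-noise injection is the identity at 0 and recoverable at 3 px", {
  s <- generate_scene(scene_spec(seed = 17))
  s0 <- inject_strong_noise(s, 0, seed = 1)
  expect_identical(s0$spectral_noisy$pixels, s$spectral_clean$pixels)

  s3 <- inject_strong_noise(s, 3, seed = 2)
  off <- attr(s3$spectral_noisy, "offsets")
  expect_true(all(abs(off) <= 3))
  # bands draw independent offsets
  expect_gt(max(dist(off)), 0)
  # the cross-correlation peak sits within 1 px of each injected offset
  for (b in 1:4) {
    est <- oracle_xcorr_offset(s3$spectral_noisy$pixels[, , b],
                               s$spectral_clean$pixels[, , b])
    expect_lt(max(abs(est - off[b, ])), 1.01)
  }
})

test_that("generate_dataset writes a 9:1-split dataset reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sp <- list(height = 24L, width = 24L)
  m1 <- generate_dataset(10, d1, spec_ranges = sp, seed = 3)
  expect_identical(sum(m1$split == "train"), 9L)
  expect_identical(sum(m1$split == "test"), 1L)
  expect_true(all(file.exists(m1$rgb)))

  m2 <- generate_dataset(10, d2, spec_ranges = sp, seed = 3)
  h1 <- tools::md5sum(sort(list.files(d1, pattern = "png$|tif$", full.names = TRUE)))
  h2 <- tools::md5sum(sort(list.files(d2, pattern = "png$|tif$", full.names = TRUE)))
  expect_identical(unname(h1), unname(h2))

  # loading restores paired rasters of the declared geometry
  ds <- load_dataset(read_manifest(file.path(d1, "manifest.csv")),
                     split = "train")
  expect_length(ds, 9L)
  expect_identical(dim(ds[[1]]$spectral$pixels), c(24L, 24L, 4L))
  expect_identical(dim(ds[[1]]$mask$labels), c(24L, 24L))
})

test_that("collapsed spec ranges yield identical scene parameters", {
  scenes <- simulate_scenes(3, list(target_veg_fraction = 0.25,
                                    blob_scale = 4), seed = 21)
  tf <- vapply(scenes, function(s) s$spec$target_veg_fraction, numeric(1))
  expect_identical(tf, rep(0.25, 3))
  seeds <- vapply(scenes, function(s) s$spec$seed, integer(1))
  expect_identical(anyDuplicated(seeds), 0L)
})
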