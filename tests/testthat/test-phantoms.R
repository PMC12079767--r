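# Synthetic age-dependent phantoms and the two corruption protocols.

test_that("phantom generation is deterministic and age trends are monotone", {
  spec <- phantom_spec()
  p1 <- generate_phantom(spec, 63, seed = 5)
  p2 <- generate_phantom(spec, 63, seed = 5)
  expect_identical(p1$image$data, p2$image$data)
  expect_identical(p1$volumes, p2$volumes)
  p3 <- generate_phantom(spec, 63, seed = 6)
  expect_false(identical(p1$image$data, p3$image$data))

  # zero jitter: ventricles strictly larger at the older age
  young <- generate_phantom(spec, 52, seed = NULL)
  old <- generate_phantom(spec, 88, seed = NULL)
  expect_gt(old$volumes[["vent"]], young$volumes[["vent"]])
  expect_lt(old$volumes[["hipp"]], young$volumes[["hipp"]])
  expect_lt(old$volumes[["gm"]], young$volumes[["gm"]])
  expect_error(generate_phantom(spec, 120), "age range")
})

test_that("label maps align with intensities and volumes are voxel counts", {
  spec <- phantom_spec()
  p <- generate_phantom(spec, 70, seed = 9)
  labs <- round(p$labels$data)
  expect_setequal(unique(as.integer(labs)), 0:4)
  for (k in 1:4) {
    expect_identical(sum(labs == k),
                     as.integer(p$volumes[[c("gm", "wm", "vent", "hipp")[k]]]))
  }
  clean <- generate_phantom(phantom_spec(), 70, seed = NULL)
  ints <- spec$intensities
  expect_true(all(clean$image$data[round(clean$labels$data) == 2] == ints[["wm"]]))
  expect_true(all(clean$image$data[round(clean$labels$data) == 0] == 0))
})

test_that("rasterized discs match their analytic area within 3%", {
  i <- matrix(0:63, 64, 64)
  j <- matrix(0:63, 64, 64, byrow = TRUE)
  for (r in c(6, 10, 14)) {
    m <- condatlas:::ellipse_mask(i, j, c(31.5, 31.5), c(r, r))
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.03)
  }
})

test_that("zero-jitter volume curves reproduce the configured area ratios", {
  # rasterization error scales with the structure perimeter, so the ratio
  # check runs on a doubled grid where boundary effects are half as large
  spec <- phantom_spec(grid = c(128L, 128L))
  v50 <- generate_phantom(spec, 50, seed = NULL)$volumes
  v90 <- generate_phantom(spec, 90, seed = NULL)$volumes
  expect_equal(v90[["vent"]] / v50[["vent"]], 1.5, tolerance = 0.04)
  expect_equal(v90[["hipp"]] / v50[["hipp"]], 0.85, tolerance = 0.04)
  expect_equal(v90[["gm"]] / v50[["gm"]], 0.90, tolerance = 0.04)
  expect_lt(v90[["wm"]], v50[["wm"]]) # mild decline via whole-brain atrophy
})

test_that("noise corruption hits the target SNR fraction", {
  spec <- phantom_spec()
  img <- generate_phantom(spec, 70, seed = 3)$image
  mask <- img$data > 0.05 * max(img$data)
  noisy <- corrupt_noise(img, 0.35, seed = 10)
  ratio <- measure_snr(noisy, mask) / measure_snr(img, mask)
  expect_gte(ratio, 0.30)
  expect_lte(ratio, 0.40)

  # snr_fraction = 1 leaves the image untouched
  expect_identical(corrupt_noise(img, 1, seed = 1)$data, img$data)

  # two seeds: different noise, same noise level within 2% (measured on a
  # larger grid so the sd estimate is tight enough for the band)
  big <- generate_phantom(phantom_spec(grid = c(128L, 128L)), 70, seed = 3)$image
  n1 <- corrupt_noise(big, 0.35, seed = 11)$data - big$data
  n2 <- corrupt_noise(big, 0.35, seed = 12)$data - big$data
  expect_false(identical(n1, n2))
  expect_lt(abs(stats::sd(n1) / stats::sd(n2) - 1), 0.02)
  expect_error(corrupt_noise(image_grid(matrix(0, 8, 8)), 0.35), "zero-signal")
})

test_that("gamma-contrast corruption draws one bounded exponent per image", {
  spec <- phantom_spec()
  img <- generate_phantom(spec, 70, seed = 3)$image
  # a -> 0 means exponent 1: unchanged
  expect_equal(corrupt_contrast(img, a = 0, seed = 1)$data, img$data,
               tolerance = 1e-15)
  # forced arithmetic: gamma = 2 maps 0.25 to 0.0625
  quarter <- image_grid(matrix(0.25, 4, 4))
  out <- corrupt_contrast(quarter, a = 0.3, seed = 2, beta = log(2))
  expect_equal(out$data, matrix(0.0625, 4, 4), tolerance = 1e-15)
  # realized exponents always within [exp(-0.3), exp(0.3)] for a = 0.3
  gammas <- vapply(1:50, function(s)
    attr(corrupt_contrast(img, a = 0.3, seed = s), "gamma"), numeric(1))
  expect_true(all(gammas >= exp(-0.3) & gammas <= exp(0.3)))
  expect_gt(stats::sd(gammas), 0)
  neg <- image_grid(matrix(-0.1, 4, 4))
  expect_error(corrupt_contrast(neg, 0.3, seed = 1), "negative")
})

test_that("the group template is the clean mid-age anatomy", {
  spec <- phantom_spec(noise_snr = 0.35, contrast_a = 0.3)
  gt <- build_group_template(spec)
  mid <- generate_phantom(phantom_spec(), mean(spec$age_range), seed = NULL)
  expect_identical(gt$image$data, mid$image$data) # noise-free despite corrupt spec
  expect_identical(gt$volumes, mid$volumes)
  gt2 <- build_group_template(spec, n_subjects = 50L, seed = 99)
  expect_identical(gt$image$data, gt2$image$data) # zero-jitter: n irrelevant

  ph <- generate_phantom(phantom_spec(), 60, seed = 4)
  flat <- image_grid(matrix(mean(gt$image$data), 64, 64))
  expect_gt(ssim(gt$image, ph$image), ssim(gt$image, flat))
})

test_that("implausible jitter triggers the retry cap", {
  spec <- phantom_spec(jitter_pos = 40)
  expect_error(generate_phantom(spec, 70, seed = 1), "overlap")
})

test_that("datasets round-trip through disk with corruption applied at write time", {
  spec <- phantom_spec(noise_snr = 0.5)
  dir <- file.path(tempdir(), "phantoms-test")
  man <- write_phantom_dataset(spec, 3, dir, seed = 44)
  expect_identical(nrow(man), 3L)
  m2 <- read_manifest(file.path(dir, "manifest.csv"))
  img <- read_image(m2$path[2])
  ds <- generate_phantom_dataset(spec, 3, seed = 44)
  expect_equal(img$data, ds$images[[2]]$data, tolerance = 1e-6)
  expect_identical(dim(img$data), c(64L, 64L))
})
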