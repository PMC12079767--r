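# Evaluation battery: Jacobian reports, SSIM, RMSD, Dice, volume trends.

test_that("jacobian_report summarises identity, scalings and smooth flows", {
  ids <- list(identity_deformation(c(12L, 12L)), identity_deformation(c(12L, 12L)))
  rep0 <- jacobian_report(ids)
  expect_equal(rep0$pooled$min, 1)
  expect_equal(rep0$pooled$max, 1)
  expect_identical(rep0$pooled$n_nonpositive, 0L)

  # uniform 2-D scaling by 1.1 -> determinant 1.21 at interior voxels
  pts <- as.matrix(expand.grid(0:15, 0:15))
  u <- 0.1 * sweep(pts, 2, c(7.5, 7.5))
  sc <- vector_field(array(u, c(16, 16, 2)), role = "deformation")
  keep <- interior_mask(c(16L, 16L), 1)
  jd <- jacobian_determinant(sc)$data
  expect_equal(max(abs(jd[keep] - 1.21)), 0, tolerance = 1e-10)

  # smooth SVF-integrated fields: no non-positive voxels
  phis <- lapply(1:5, function(s)
    integrate_svf(smooth_velocity(c(24L, 24L), max_mag = 2, seed = s)))
  repS <- jacobian_report(phis)
  expect_identical(repS$pooled$n_nonpositive, 0L)
  expect_identical(nrow(repS$per_field), 5L)
  expect_error(jacobian_report(list()), "empty")
})

test_that("SSIM is 1 on identical images, symmetric, and orders degradations", {
  set.seed(15)
  base <- generate_phantom(phantom_spec(), 70, seed = 2)$image
  expect_equal(ssim(base, base), 1, tolerance = 1e-12)
  other <- generate_phantom(phantom_spec(), 55, seed = 3)$image
  expect_equal(ssim(base, other), ssim(other, base), tolerance = 1e-12)
  expect_lte(ssim(base, other), 1)

  noisy <- image_grid(base$data + matrix(stats::rnorm(4096, sd = 0.25), 64, 64))
  blurred <- image_grid(condatlas:::gauss_filter2(base$data, 1, 5))
  expect_lt(ssim(base, noisy), ssim(base, blurred))
  expect_lt(ssim(base, noisy), 1)
  # not 1 for a constant intensity shift
  expect_lt(ssim(base, image_grid(base$data + 0.2)), 1)
})

test_that("RMSD matches brute force and behaves like a metric", {
  set.seed(16)
  x <- image_grid(matrix(stats::runif(100), 10, 10))
  y <- image_grid(matrix(stats::runif(100), 10, 10))
  z <- image_grid(matrix(stats::runif(100), 10, 10))
  expect_identical(rmsd(x, x), 0)
  expect_equal(rmsd(x, image_grid(x$data - 0.37)), 0.37, tolerance = 1e-12)
  expect_equal(rmsd(x, y), sqrt(mean((x$data - y$data)^2)), tolerance = 1e-12)
  for (i in 1:5) { # triangle inequality on random triples
    a <- image_grid(matrix(stats::runif(100), 10, 10))
    b <- image_grid(matrix(stats::runif(100), 10, 10))
    c <- image_grid(matrix(stats::runif(100), 10, 10))
    expect_lte(rmsd(a, c), rmsd(a, b) + rmsd(b, c) + 1e-12)
  }
})

test_that("Dice hits the forced overlap cases and reports absent labels as NA", {
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10)
  a[1:4, 1:4] <- 1; b[1:4, 1:4] <- 1          # identical
  a[6:9, 1:2] <- 2; b[6:9, 9:10] <- 2         # disjoint, equal size
  a[1:4, 6:9] <- 3; b[3:6, 6:9] <- 3          # |A| = |B| = 16, overlap 8
  d <- dice(image_grid(a), image_grid(b), labels = 1:4)
  expect_equal(unname(d["1"]), 1)
  expect_equal(unname(d["2"]), 0)
  expect_equal(unname(d["3"]), 0.5)
  expect_true(is.na(d["4"]))
})

test_that("normalized volumes always average to one per ROI and method", {
  expect_equal(normalized_volumes(c(2, 4, 6)), c(0.5, 1, 1.5))
  expect_equal(normalized_volumes(rep(7, 5)), rep(1, 5))
  set.seed(17)
  df <- expand.grid(method = c("a", "b"), roi = c("r1", "r2"), age = 1:7)
  df$volume <- stats::runif(nrow(df), 10, 100)
  out <- normalized_volumes(df)
  agg <- stats::aggregate(vnorm ~ method + roi, out, mean)
  expect_equal(agg$vnorm, rep(1, 4), tolerance = 1e-12)
  expect_error(normalized_volumes(c(1, -2)), "positive")
})

test_that("binned reference curves normalize per the bin-mean convention", {
  one <- data.frame(age = stats::runif(20, 60, 61.9), volume = stats::runif(20))
  b1 <- binned_reference_volumes(one, bin_width = 2)
  expect_equal(b1$vnorm[is.finite(b1$vnorm)], 1)

  two <- data.frame(age = c(rep(60.5, 4), rep(62.5, 4)),
                    volume = c(rep(10, 4), rep(30, 4)))
  b2 <- binned_reference_volumes(two, bin_width = 2, age_range = c(60, 64))
  expect_equal(sort(b2$vnorm[is.finite(b2$vnorm)]), c(0.5, 1.5))

  gap <- data.frame(age = c(rep(50.5, 3), rep(56.5, 3)),
                    volume = c(1, 1, 1, 3, 3, 3))
  b3 <- binned_reference_volumes(gap, bin_width = 2, age_range = c(50, 58))
  expect_true(any(b3$n == 0))
  expect_true(all(is.na(b3$vnorm[b3$n == 0]))) # empty bins missing, not imputed
})

test_that("phantom volume curves with zero jitter recover the generating slopes", {
  spec <- phantom_spec()
  ages <- seq(50, 90, by = 2)
  vols <- do.call(rbind, lapply(ages, function(a) {
    v <- generate_phantom(spec, a, seed = NULL)$volumes
    data.frame(age = a, roi = c("vent", "hipp"), volume = c(v[["vent"]], v[["hipp"]]))
  }))
  ref <- binned_reference_volumes(vols, bin_width = 2)
  vent <- ref[ref$roi == "vent" & is.finite(ref$vnorm), ]
  fit <- stats::lm(vnorm ~ bin_centre, vent)
  # analytic normalized slope of a linear area factor over 50..90
  f <- condatlas:::age_factor(c(50, 90), c(50, 90), spec$vent_change)
  slope_true <- diff(f) / 40 / mean(f)
  expect_equal(unname(stats::coef(fit)[2]), slope_true, tolerance = 0.15)
  expect_gt(stats::cor(vent$vnorm, vent$bin_centre, method = "spearman"), 0.95)
})

test_that("trend recovery reports direction, rank correlation and the largest gap", {
  curve <- data.frame(age = seq(50, 90, 5), vnorm = seq(0.8, 1.2, length.out = 9))
  same <- trend_recovery(curve, curve)
  expect_true(same$sign_agreement)
  expect_equal(same$spearman, 1)
  expect_equal(same$max_gap, 0)
  rev <- data.frame(age = curve$age, vnorm = rev(curve$vnorm))
  opp <- trend_recovery(curve, rev)
  expect_equal(opp$spearman, -1)
  expect_false(opp$sign_agreement)
  expect_error(trend_recovery(curve[1:2, ], curve), "3 support")
})

test_that("the internal SVF registration aligns shifted anatomy and helps SSIM", {
  spec <- phantom_spec()
  fixed <- generate_phantom(spec, 60, seed = NULL)$image
  moving <- generate_phantom(spec, 75, seed = NULL)$image
  pre <- ssim(fixed, moving)
  reg <- register_pair(fixed, moving, iters = 120)
  expect_gt(ssim(fixed, reg$warped), pre)
  expect_lt(utils::tail(reg$trace, 1), reg$trace[1])
  # the fitted deformation stays diffeomorphic
  jd <- jacobian_determinant(reg$phi)$data
  expect_gt(min(jd[interior_mask(c(64L, 64L), 2)]), 0)
})

test_that("template volume measurement counts warped group-template labels", {
  spec <- phantom_spec()
  gt <- build_group_template(spec)
  cfg <- ct_config(epochs = 1L)
  model <- init_model(cfg, seed = 51)
  tracker <- condatlas:::default_tracker(model)
  tps <- build_templates(model, tracker, gt$image, c(60, 80))
  tv <- template_volumes(tps, gt$labels)
  # identity deformations (zero-init heads): volumes equal the template's
  for (r in c("gm", "wm", "vent", "hipp")) {
    expect_true(all(tv$volume[tv$roi == r] == gt$volumes[[r]]))
  }
})
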