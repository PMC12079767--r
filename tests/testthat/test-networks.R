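# Network construction, forward passes, template export, backprop correctness.

test_that("stage-1 deterministic path is bitwise reproducible; sampling is seeded", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 3)
  set.seed(4)
  model$params <- model$params + stats::rnorm(length(model$params), sd = 0.02)
  v1 <- stage1_forward(model, 70, sample = FALSE)
  v2 <- stage1_forward(model, 70, sample = FALSE)
  expect_identical(v1$data, v2$data)
  s1 <- stage1_forward(model, 70, sample = TRUE, seed = 11)
  s2 <- stage1_forward(model, 70, sample = TRUE, seed = 11)
  s3 <- stage1_forward(model, 70, sample = TRUE, seed = 12)
  expect_identical(s1$data, s2$data)
  expect_false(identical(s1$data, s3$data))
})

test_that("untrained networks emit finite velocity fields on the model grid", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 4)
  for (a in c(50, 64.2, 90)) {
    v <- stage1_forward(model, a)
    expect_identical(dim(v$data), c(16L, 16L, 2L))
    expect_true(all(is.finite(v$data)))
  }
  set.seed(5)
  Ta <- image_grid(matrix(stats::runif(256), 16, 16))
  X <- image_grid(matrix(stats::runif(256), 16, 16))
  v2a <- stage2_forward(model, Ta, X)
  v2b <- stage2_forward(model, Ta, X)
  expect_identical(v2a$data, v2b$data)
  expect_identical(dim(v2a$data), c(16L, 16L, 2L))
  expect_error(stage2_forward(model, Ta, image_grid(matrix(0, 8, 8))),
               "different grids")
  expect_error(stage1_forward(model, NaN), "finite")
})

test_that("zero-initialized heads start from identity deformations", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 6)
  # velocity heads are zero-initialized: stage-1 output is exactly zero
  expect_identical(as.numeric(stage1_forward(model, 70)$data), rep(0, 512))
  tracker <- condatlas:::default_tracker(model)
  gt <- image_grid(matrix(stats::runif(256), 16, 16))
  tp <- build_templates(model, tracker, gt, 70)[[1]]
  expect_identical(tp$template$data, gt$data)   # zero-velocity warp
  expect_identical(tp$template$data, tp$template_adj$data)
})

test_that("templates and adjusted templates coincide when tracked means are zero", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 7)
  # make stage-1 non-trivial by perturbing all parameters
  set.seed(8)
  model$params <- model$params + stats::rnorm(length(model$params), sd = 0.02)
  tracker <- condatlas:::default_tracker(model)
  gt <- image_grid(matrix(stats::runif(256), 16, 16))
  tps <- build_templates(model, tracker, gt, c(55, 70, 85))
  for (tp in tps) {
    expect_identical(tp$template$data, tp$template_adj$data)
    expect_identical(tp$phi$data, tp$phi_adj$data)
    expect_true(all(is.finite(tp$template$data)))
  }
  # out-of-range ages clamp with a warning
  expect_warning(build_templates(model, tracker, gt, 120), "clamping")
})

test_that("backpropagated gradients match finite differences on the full loss", {
  cfg <- tiny_config()
  ecfg <- condatlas:::engine_cfg(cfg)
  lay <- condatlas:::ca_param_layout_cpp(ecfg)
  set.seed(12)
  params <- stats::rnorm(lay$total, sd = 0.1)
  Tm <- matrix(stats::runif(256), 16, 16)
  X <- matrix(stats::runif(256), 16, 16)
  m0 <- stats::rnorm(128, sd = 0.05)
  m1 <- stats::rnorm(128, sd = 0.05)
  eps <- stats::rnorm(cfg$latent)
  gam <- cfg$gammas
  run <- function(p, grad = FALSE) {
    gbuf <- numeric(lay$total)
    r <- condatlas:::ca_model_run_cpp(ecfg, p, gbuf, Tm, X, 0.3, eps, TRUE,
                                      m0, m1, 0.7, 0.3, 0.1, TRUE, TRUE,
                                      gam, FALSE, grad, TRUE)
    list(loss = r$total, grad = gbuf)
  }
  r0 <- run(params, grad = TRUE)
  set.seed(13)
  idx <- sample(lay$total, 50)
  for (i in idx) {
    d <- 1e-6
    pp <- params; pp[i] <- pp[i] + d
    pm <- params; pm[i] <- pm[i] - d
    fd <- (run(pp)$loss - run(pm)$loss) / (2 * d)
    an <- r0$grad[i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
  }
})
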