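# Optimization loop: loss decrease, determinism, ablation, checkpoint resume.

make_tiny_dataset <- function(n = 10, seed = 31) {
  spec <- tiny_spec(jitter_size = 0.05, jitter_pos = 0.5)
  generate_phantom_dataset(spec, n, seed = seed)
}

test_that("reconstruction alone drives velocities toward zero on self-scans", {
  # every scan equals the template, so the optimum is the identity transform;
  # start from a perturbed model and check that the reconstruction loss and
  # the velocity magnitudes shrink over 50 steps
  cfg <- tiny_config(lr = 1e-3, batch_size = 5, seed = 21,
                     gammas = c(1, 0, 0, 0, 0, 0))
  spec <- tiny_spec()
  gt <- build_group_template(spec)
  set.seed(22)
  model <- init_model(cfg)
  model$params <- model$params + stats::rnorm(length(model$params), sd = 0.05)
  tracker <- condatlas:::default_tracker(model)
  opt <- condatlas:::adamw_init(length(model$params))
  tmpl <- condatlas:::as_matrix2(gt$image)
  batch <- lapply(seq(52, 88, length.out = 5),
                  function(a) list(X = tmpl, alpha = a))
  v0 <- mean(abs(stage1_forward(model, 70)$data))
  recon <- numeric(50)
  for (k in 1:50) {
    st <- train_step(model, tracker, batch, tmpl, opt)
    model <- st$model; tracker <- st$tracker; opt <- st$opt
    recon[k] <- st$losses$components[["recon"]]
  }
  expect_lt(recon[50], recon[1])
  expect_lt(mean(abs(stage1_forward(model, 70)$data)), v0)
})

test_that("training is bitwise deterministic given config, data and seed", {
  cfg <- tiny_config(lr = 1e-3, batch_size = 4, epochs = 3, seed = 33)
  ds <- make_tiny_dataset()
  ck1 <- run_training(ds, cfg)
  ck2 <- run_training(ds, cfg)
  expect_identical(ck1$loss_log, ck2$loss_log)
  expect_identical(ck1$model$params, ck2$model$params)
  expect_identical(ck1$tracker$means, ck2$tracker$means)
})

test_that("with all loss weights zero only weight decay moves the parameters", {
  cfg <- tiny_config(lr = 1e-3, batch_size = 5, epochs = 2, seed = 35,
                     gammas = rep(0, 6))
  ds <- make_tiny_dataset(n = 5)
  ck <- run_training(ds, cfg)
  expect_true(all(ck$loss_log$total == 0))
  set.seed(cfg$seed)
  p0 <- init_model(cfg)$params
  steps <- ck$opt$t
  expect_equal(ck$model$params, p0 * (1 - cfg$lr * cfg$weight_decay)^steps,
               tolerance = 1e-12)
})

test_that("training resumed from a checkpoint reproduces the uninterrupted run", {
  ds <- make_tiny_dataset()
  cfg4 <- tiny_config(lr = 1e-3, batch_size = 4, epochs = 4, seed = 37)
  full <- run_training(ds, cfg4)
  cfg2 <- cfg4; cfg2$epochs <- 2L
  half <- run_training(ds, cfg2)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(half, path)
  resumed <- run_training(ds, cfg4, resume = load_checkpoint(path))
  expect_identical(resumed$model$params, full$model$params)
  expect_identical(resumed$loss_log, full$loss_log)
})

test_that("template export is identical before and after checkpoint round-trip", {
  ds <- make_tiny_dataset()
  cfg <- tiny_config(lr = 1e-3, batch_size = 4, epochs = 2, seed = 39)
  ck <- run_training(ds, cfg)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  gt <- build_group_template(tiny_spec())
  t1 <- build_templates(ck$model, ck$tracker, gt$image, c(55, 75))
  t2 <- build_templates(ck2$model, ck2$tracker, gt$image, c(55, 75))
  expect_identical(t1[[1]]$template$data, t2[[1]]$template$data)
  expect_identical(t1[[2]]$phi$data, t2[[2]]$phi$data)
})

test_that("the ablation sweep zeroes one weight per run and keeps seeds fixed", {
  ds <- make_tiny_dataset(n = 6)
  cfg <- tiny_config(lr = 1e-3, batch_size = 3, epochs = 2, seed = 41)
  runs <- run_ablation(ds, cfg, which = c(3, 6))
  expect_named(runs, c("full", "gamma3=0", "gamma6=0"))
  expect_identical(runs[["gamma3=0"]]$gammas[3], 0)
  expect_identical(runs[["gamma6=0"]]$gammas[6], 0)
  # the ablated runs still optimize (losses logged, finite)
  for (r in runs) expect_true(all(is.finite(r$loss_log$total)))
  expect_error(run_ablation(ds, cfg, which = 1), "2..6")
})

test_that("degenerate training inputs are rejected", {
  cfg <- tiny_config()
  expect_error(run_training(list(template = matrix(0, 16, 16), images = list(),
                                 alphas = numeric(0)), cfg),
               "no images")
})
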