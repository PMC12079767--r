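#' @title Joint training of the two-stage model
#' @description Optimizes both network stages under the six-term weighted loss
#'   with AdamW (decoupled weight decay), updating the soft-binned tracker of
#'   local mean Stage-2 velocities once per training sample in the forward
#'   pass. A single master seed fans out (through R's RNG stream) to weight
#'   initialization, batch shuffling and latent sampling, so a run is
#'   reproducible from `(config, data, seed)`.
#' @name trainer
NULL

adamw_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

adamw_step <- function(params, grad, opt, cfg) {
  opt$t <- opt$t + 1L
  opt$m <- cfg$beta1 * opt$m + (1 - cfg$beta1) * grad
  opt$v <- cfg$beta2 * opt$v + (1 - cfg$beta2) * grad^2
  mhat <- opt$m / (1 - cfg$beta1^opt$t)
  vhat <- opt$v / (1 - cfg$beta2^opt$t)
  params <- params - cfg$lr * (mhat / (sqrt(vhat) + 1e-8) +
                               cfg$weight_decay * params)
  list(params = params, opt = opt)
}

#' One optimizer step on a batch
#'
#' Per sample: the Stage-1 velocity is predicted from the covariate and
#' integrated; the group template is warped into the conditional template;
#' Stage 2 predicts the registration velocity from (template, scan); its flow
#' warps the template into the predicted scan; the tracker is updated with
#' the Stage-2 velocity; the mean-adjusted template is built from the
#' combined velocity; all six loss components are evaluated. Gradients are
#' averaged over the batch and one AdamW step is taken.
#'
#' @param model a `ct_model`.
#' @param tracker the `bin_tracker` (velocity-resolution grid).
#' @param batch list of samples, each `list(X = <image matrix>, alpha = <age>)`
#'   (optionally `alpha` a vector with sex appended).
#' @param template group template as a matrix on the model grid.
#' @param opt AdamW state from `adamw_init()`.
#' @param gammas optional override of the loss weights (ablation runs).
#' @return `list(model, tracker, opt, losses)` where `losses` is the
#'   batch-mean `loss_bundle`.
#' @export
train_step <- function(model, tracker, batch, template, opt,
                       gammas = model$cfg$gammas) {
  cfg <- model$cfg
  grad <- numeric(length(model$params))
  acc <- numeric(7)
  for (s in batch) {
    pr <- tracker_pair(tracker, s$alpha[1])
    eps <- if (cfg$sample_latent) stats::rnorm(cfg$latent) else numeric(cfg$latent)
    r <- ca_model_run_cpp(engine_cfg(cfg), model$params, grad,
                          template, s$X,
                          normalize_covariate(cfg, s$alpha), eps,
                          cfg$sample_latent,
                          as.numeric(tracker$means[[pr$k[1]]]),
                          as.numeric(tracker$means[[pr$k[2]]]),
                          pr$z[1], pr$z[2], cfg$lambda, TRUE,
                          cfg$mean_gradient == "sample",
                          gammas, cfg$mean_loss == "l1", TRUE, TRUE)
    comp <- c(r$recon, r$bend1, r$bend2, r$disp1, r$disp2, r$mean, r$total)
    if (any(!is.finite(comp))) {
      nm <- c("recon", "bend1", "bend2", "disp1", "disp2", "mean", "total")
      stop("non-finite loss component: ",
           paste(nm[!is.finite(comp)], collapse = ", "))
    }
    acc <- acc + comp
    tracker$means[[pr$k[1]]] <- array(r$newm0, dim(tracker$means[[pr$k[1]]]))
    tracker$means[[pr$k[2]]] <- array(r$newm1, dim(tracker$means[[pr$k[2]]]))
  }
  n <- length(batch)
  grad <- grad / n
  st <- adamw_step(model$params, grad, opt, cfg)
  model$params <- st$params
  acc <- acc / n
  list(model = model, tracker = tracker, opt = st$opt,
       losses = loss_bundle(acc[1], acc[2], acc[3], acc[4], acc[5], acc[6],
                            weights = gammas))
}

#' Train the full model on a dataset
#'
#' @param dataset a list with elements `template` (matrix or `image_grid` on
#'   the model grid), `images` (list of matrices / `image_grid`s), and
#'   `alphas` (per-image covariates; ages, or rows of age + sex). Built from a
#'   manifest with [load_dataset()] or in memory with
#'   [generate_phantom_dataset()].
#' @param cfg a [ct_config()].
#' @param gammas optional loss-weight override (used by the ablation sweep).
#' @param log_path optional CSV path for the per-epoch loss log.
#' @param resume optional checkpoint to continue from (restores parameters,
#'   optimizer and tracker state, epoch counter and the RNG stream, so the
#'   continued run reproduces an uninterrupted one).
#' @param verbose print per-epoch losses.
#' @return a checkpoint: `list(model, tracker, opt, cfg, gammas, loss_log,
#'   step_log, epoch, rng_state)`; `loss_log` holds per-epoch means and
#'   `step_log` per-optimizer-step component values (both written as CSV when
#'   `log_path` is given).
#' @export
run_training <- function(dataset, cfg, gammas = cfg$gammas, log_path = NULL,
                         resume = NULL, verbose = FALSE) {
  template <- dataset$template
  if (inherits(template, "image_grid")) template <- as_matrix2(template)
  if (length(dataset$images) == 0) stop("dataset contains no images")
  images <- lapply(dataset$images, function(x) {
    if (inherits(x, "image_grid")) as_matrix2(x) else x
  })
  alphas <- dataset$alphas
  if (is.null(dim(alphas))) alphas <- matrix(alphas, ncol = 1)

  if (is.null(resume)) {
    set.seed(cfg$seed)
    model <- init_model(cfg, seed = NULL) # consumes the seeded stream
    tracker <- default_tracker(model)
    opt <- adamw_init(length(model$params))
    loss_log <- NULL
    step_log <- NULL
    epoch0 <- 0L
  } else {
    model <- resume$model
    tracker <- resume$tracker
    opt <- resume$opt
    loss_log <- resume$loss_log
    step_log <- resume$step_log
    epoch0 <- resume$epoch
    assign(".Random.seed", resume$rng_state, envir = globalenv())
  }

  n <- length(images)
  for (epoch in seq.int(epoch0 + 1L, length.out = cfg$epochs - epoch0)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    esum <- numeric(7)
    for (b in batches) {
      batch <- lapply(b, function(i) list(X = images[[i]], alpha = alphas[i, ]))
      st <- train_step(model, tracker, batch, template, opt, gammas = gammas)
      model <- st$model; tracker <- st$tracker; opt <- st$opt
      comp <- c(st$losses$components, total = st$losses$total)
      step_log <- rbind(step_log,
                        data.frame(epoch = epoch, step = st$opt$t,
                                   as.list(comp)))
      esum <- esum + comp * length(b)
    }
    esum <- esum / n
    row <- data.frame(epoch = epoch, recon = esum[1], bend1 = esum[2],
                      bend2 = esum[3], disp1 = esum[4], disp2 = esum[5],
                      mean = esum[6], total = esum[7])
    loss_log <- rbind(loss_log, row)
    if (verbose)
      message(sprintf("epoch %3d  total %.6f  recon %.6f  mean %.6f",
                      epoch, esum[7], esum[1], esum[6]))
  }
  if (!is.null(log_path)) {
    utils::write.csv(loss_log, log_path, row.names = FALSE)
    utils::write.csv(step_log, sub("(\\.csv)?$", "_steps.csv", log_path),
                     row.names = FALSE)
  }
  structure(list(model = model, tracker = tracker, opt = opt, cfg = cfg,
                 gammas = gammas, loss_log = loss_log, step_log = step_log,
                 epoch = cfg$epochs,
                 rng_state = get(".Random.seed", envir = globalenv())),
            class = "ct_checkpoint")
}

#' @export
print.ct_checkpoint <- function(x, ...) {
  cat("<ct_checkpoint> epoch ", x$epoch, " | final total loss ",
      signif(utils::tail(x$loss_log$total, 1), 6), "\n", sep = "")
  invisible(x)
}

#' Save / load a checkpoint (model weights, tracker state, optimizer state,
#' configuration and RNG stream)
#'
#' @param ckpt a checkpoint from [run_training()].
#' @param path file path.
#' @export
save_checkpoint <- function(ckpt, path) {
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  readRDS(path)
}

#' Loss-weight ablation sweep
#'
#' Re-trains the model once per ablated weight, setting each of the
#' smoothness/magnitude/mean weights (positions 2--6) to zero in turn while
#' keeping data, seed and every other setting identical. Position 1 (the
#' reconstruction weight) is never ablated.
#'
#' @param dataset as in [run_training()].
#' @param cfg a [ct_config()].
#' @param which integer positions in 2..6 to ablate (default all).
#' @param verbose print progress.
#' @return named list of checkpoints (`"full"` plus `"gamma<k>=0"` entries).
#' @export
run_ablation <- function(dataset, cfg, which = 2:6, verbose = FALSE) {
  if (any(which < 2 | which > 6)) stop("only positions 2..6 can be ablated")
  out <- list(full = run_training(dataset, cfg, verbose = verbose))
  for (k in which) {
    g <- cfg$gammas
    g[k] <- 0
    out[[paste0("gamma", k, "=0")]] <-
      run_training(dataset, cfg, gammas = g, verbose = verbose)
  }
  out
}
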