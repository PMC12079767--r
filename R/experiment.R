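#' Desk-scale study conditions
#'
#' The package's reference synthetic experiment: 200 phantoms on a 64x64
#' grid with ages uniform over 50--90 years, ventricle area increasing 50%
#' across the range, hippocampus decreasing 15% and cortical grey matter 10%
#' (white matter declining mildly), subject jitter on, no corruption. The
#' training configuration uses the standard loss weights and AdamW moments
#' with a desk-scale learning rate of 1e-3, batch size 8 and 40 epochs;
#' tracker bins sit every 5 years over the age range. The methods vignette
#' discusses these choices.
#'
#' @param n number of phantom subjects.
#' @param seed master seed for ages, jitter and corruption.
#' @return `study_dataset()`: a dataset list (see
#'   [generate_phantom_dataset()]) with the `phantom_spec` attached as
#'   attribute `"spec"`.
#' @export
study_dataset <- function(n = 200L, seed = 42L) {
  spec <- phantom_spec()
  ds <- generate_phantom_dataset(spec, n, seed = seed)
  attr(ds, "spec") <- spec
  ds
}

#' @rdname study_dataset
#' @return `study_config()`: the corresponding [ct_config()].
#' @export
study_config <- function(seed = 7L) {
  ct_config(lr = 1e-3, batch_size = 8L, epochs = 40L, seed = as.integer(seed),
            bin_centres = seq(50, 90, by = 5), cov_bounds = c(50, 90))
}

#' Per-bin mean Stage-2 displacement magnitude
#'
#' For every training scan the Stage-2 registration deformation (from its
#' conditional template to the scan) is computed and soft-binned by age with
#' the tracker's triangular weights; within each bin the displacement fields
#' are averaged as vectors and the mean magnitude of that average field is
#' reported. A centred model leaves little systematic per-bin deformation, so
#' smaller values indicate better-centred conditional templates.
#'
#' @param ckpt a checkpoint from [run_training()].
#' @param dataset the training dataset.
#' @param group_template the group template `image_grid`.
#' @return data.frame with `bin_centre`, `weight` (total soft weight) and
#'   `mean_disp` (voxels).
#' @export
stage2_bin_mean_displacement <- function(ckpt, dataset, group_template) {
  model <- ckpt$model
  tracker <- ckpt$tracker
  cents <- tracker$centres
  sums <- lapply(cents, function(c) 0)
  wts <- numeric(length(cents))
  alphas <- dataset$alphas
  if (!is.null(dim(alphas))) alphas <- alphas[, 1]
  for (i in seq_along(dataset$images)) {
    a <- alphas[i]
    tp <- build_templates(model, tracker, group_template, a)[[1]]
    img <- dataset$images[[i]]
    if (!inherits(img, "image_grid")) img <- image_grid(img)
    v2 <- stage2_forward(model, tp$template, img)
    u2 <- integrate_svf(v2, model$cfg$steps)
    w <- bin_weights(tracker, a)
    for (k in which(w > 0)) {
      sums[[k]] <- sums[[k]] + w[k] * u2$data
      wts[k] <- wts[k] + w[k]
    }
  }
  md <- vapply(seq_along(cents), function(k) {
    if (wts[k] == 0) return(NA_real_)
    m <- sums[[k]] / wts[k]
    mean(sqrt(m[, , 1]^2 + m[, , 2]^2))
  }, numeric(1))
  data.frame(bin_centre = cents, weight = wts, mean_disp = md)
}

#' Reference volume curves of a phantom dataset
#'
#' Binned normalized volume curves (2-year bins) of the true per-subject
#' structure volumes carried by a phantom dataset.
#'
#' @param dataset a dataset from [generate_phantom_dataset()].
#' @param rois structure names to include.
#' @param bin_width bin width in years.
#' @return a [binned_reference_volumes()] table.
#' @export
study_reference_curves <- function(dataset, rois = c("gm", "wm", "vent", "hipp"),
                                   bin_width = 2) {
  vols <- do.call(rbind, lapply(rois, function(r)
    data.frame(age = dataset$volumes$age, roi = r,
               volume = dataset$volumes[[r]])))
  binned_reference_volumes(vols, bin_width = bin_width)
}
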