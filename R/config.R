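#' Model and training configuration
#'
#' One configuration object drives network construction, training and
#' template export, and round-trips through YAML. Defaults follow the
#' reference training setup where stated (AdamW with learning rate 1e-4,
#' beta1 0.9, beta2 0.999, weight decay 1e-2; loss weights
#' gamma = (1, 0.01, 0.01, 0.01, 0.01, 1); tracker update rate lambda 0.1;
#' bin centres every 5 years) and otherwise use the package's desk-scale
#' 2-D architecture: a 64x64 grid, latent dimension 16, U-Net encoder widths
#' (16, 32, 32, 32), velocities predicted at half resolution, 7
#' scaling-and-squaring steps.
#'
#' @param grid image grid (square, divisible by 8); velocities live on
#'   `grid / 2`.
#' @param cov_dim covariate dimension (1 for age, 2 for age + sex).
#' @param cov_bounds ages mapped linearly to \[-1, 1\] over this range; sex,
#'   when present, is encoded as +/-1.
#' @param latent latent dimension of the Stage-1 generator.
#' @param s1_hidden width of the fully connected encoder layer.
#' @param s1_ch0,s1_g0,s1_up_ch Stage-1 decoder: starting channels/grid and
#'   transpose-convolution output channels (each doubles the grid).
#' @param s2_ch U-Net encoder widths (4 levels).
#' @param steps scaling-and-squaring steps.
#' @param lr,beta1,beta2,weight_decay AdamW hyperparameters.
#' @param epochs,batch_size,seed training loop controls.
#' @param gammas the six loss weights (recon, bend1, bend2, disp1, disp2,
#'   mean).
#' @param lambda tracker update rate in (0, 1).
#' @param bin_centres tracker bin centres (years).
#' @param mean_loss `"mse"` or `"l1"` form of the mean-consistency penalty.
#' @param mean_gradient `"sample"` routes the gradient of the mean-consistency
#'   penalty through the current sample's contribution to the tracked mean;
#'   `"none"` treats the update as fully detached.
#' @param sample_latent draw the latent by reparameterisation during training
#'   (deterministic mean is always used for template export).
#' @param latent_logvar_init initial bias of the latent log-variance head.
#'   A moderately negative value starts training with small latent noise so
#'   the covariate signal is not swamped early on; the variance remains
#'   learnable.
#' @param kl_weight optional weight of a latent KL penalty (0 disables it; the
#'   printed loss has no divergence term).
#' @return an object of class `ct_config`.
#' @export
ct_config <- function(grid = c(64L, 64L),
                      cov_dim = 1L,
                      cov_bounds = c(50, 90),
                      latent = 16L,
                      s1_hidden = 32L,
                      s1_ch0 = 32L,
                      s1_g0 = 4L,
                      s1_up_ch = c(32L, 32L, 16L),
                      s2_ch = c(16L, 32L, 32L, 32L),
                      steps = 7L,
                      lr = 1e-4,
                      beta1 = 0.9,
                      beta2 = 0.999,
                      weight_decay = 1e-2,
                      epochs = 40L,
                      batch_size = 4L,
                      seed = 1L,
                      gammas = c(1, 0.01, 0.01, 0.01, 0.01, 1),
                      lambda = 0.1,
                      bin_centres = seq(55, 85, by = 5),
                      mean_loss = c("mse", "l1"),
                      mean_gradient = c("sample", "none"),
                      sample_latent = TRUE,
                      latent_logvar_init = -3,
                      kl_weight = 0) {
  mean_loss <- match.arg(mean_loss)
  mean_gradient <- match.arg(mean_gradient)
  if (lr <= 0) stop("learning rate must be positive")
  if (length(gammas) != 6 || any(gammas < 0)) stop("gammas must be six non-negative weights")
  if (lambda <= 0 || lambda >= 1) stop("lambda must lie in (0, 1)")
  if (cov_bounds[1] >= cov_bounds[2]) stop("cov_bounds must satisfy min < max")
  cfg <- list(grid = as.integer(grid), cov_dim = as.integer(cov_dim),
              cov_bounds = as.numeric(cov_bounds),
              latent = as.integer(latent), s1_hidden = as.integer(s1_hidden),
              s1_ch0 = as.integer(s1_ch0), s1_g0 = as.integer(s1_g0),
              s1_up_ch = as.integer(s1_up_ch), s2_ch = as.integer(s2_ch),
              steps = as.integer(steps), lr = lr, beta1 = beta1, beta2 = beta2,
              weight_decay = weight_decay, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), seed = as.integer(seed),
              gammas = as.numeric(gammas), lambda = lambda,
              bin_centres = as.numeric(bin_centres), mean_loss = mean_loss,
              mean_gradient = mean_gradient, sample_latent = sample_latent,
              latent_logvar_init = latent_logvar_init, kl_weight = kl_weight)
  class(cfg) <- "ct_config"
  cfg
}

#' @export
print.ct_config <- function(x, ...) {
  cat("<ct_config> grid ", paste(x$grid, collapse = "x"),
      " | latent ", x$latent, " | epochs ", x$epochs,
      " | lr ", x$lr, " | gammas ", paste(x$gammas, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param overrides named list of values overriding the file (mirrors
#'   command-line flag overrides).
#' @return a `ct_config`.
#' @export
read_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(ct_config, vals[names(vals) %in% names(formals(ct_config))])
}

#' @rdname read_config
#' @param cfg a `ct_config` to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
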