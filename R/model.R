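#' Initialize the two-stage conditional template network
#'
#' Stage 1 maps the (normalized) covariate through fully connected layers to
#' the mean and log-variance of a latent code, then decodes the code with
#' transpose convolutions into a conditional stationary velocity field.
#' Stage 2 is a U-Net over the two-channel (conditional template, participant
#' scan) image that predicts the registration velocity field. Both velocity
#' heads are zero-initialized so training starts from identity deformations;
#' remaining weights use He-scaled Gaussian initialization. Velocities are
#' predicted at half the image resolution and integrated there; deformations
#' are upsampled to the full grid before warping.
#'
#' @param cfg a [ct_config()].
#' @param seed optional integer seed for weight initialization (defaults to
#'   `cfg$seed`).
#' @return an object of class `ct_model` holding the flat parameter vector and
#'   its layout.
#' @export
init_model <- function(cfg, seed = NULL) {
  layout <- ca_param_layout_cpp(engine_cfg(cfg))
  params <- numeric(layout$total)
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(layout$names)) {
    nm <- layout$names[i]
    n <- layout$rows[i] * layout$cols[i]
    at <- layout$offsets[i] + seq_len(n)
    if (grepl("\\.b$", nm) || grepl("head", nm)) {
      params[at] <- if (nm == "s1.lv.b") cfg$latent_logvar_init else 0
    } else {
      fan_in <- if (grepl("^s1\\.up", nm)) {
        # transpose conv (Cin*Cout x 16): each output taps Cin * 4 inputs
        layout$rows[i] / s1_out_channels(cfg, nm) * 4
      } else if (grepl("enc|dec|s2\\.", nm)) {
        layout$rows[i]            # conv im2col weight: rows = Cin * 9
      } else {
        layout$cols[i]            # fully connected (out x in)
      }
      params[at] <- stats::rnorm(n, sd = sqrt(2 / fan_in))
    }
  }
  structure(list(cfg = cfg, layout = layout, params = params),
            class = "ct_model")
}

s1_out_channels <- function(cfg, nm) {
  i <- as.integer(sub("^s1\\.up([0-9]+)\\..*$", "\\1", nm))
  cfg$s1_up_ch[i]
}

engine_cfg <- function(cfg) {
  cfg[c("grid", "cov_dim", "latent", "s1_hidden", "s1_ch0", "s1_g0",
        "s1_up_ch", "s2_ch", "steps")]
}

#' @export
print.ct_model <- function(x, ...) {
  cat("<ct_model> ", length(x$params), " parameters | grid ",
      paste(x$cfg$grid, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Normalize a covariate vector for the network
#'
#' Age is mapped linearly to \[-1, 1\] over `cov_bounds` (values outside are
#' clipped); sex, when present, is passed through as +/-1.
#'
#' @param cfg a `ct_config`.
#' @param alpha covariate vector (age first).
#' @return normalized covariate vector of length `cov_dim`.
#' @keywords internal
normalize_covariate <- function(cfg, alpha) {
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha))) stop("covariate values must be finite")
  b <- cfg$cov_bounds
  a1 <- 2 * (min(max(alpha[1], b[1]), b[2]) - b[1]) / (b[2] - b[1]) - 1
  out <- c(a1, alpha[-1])
  if (length(out) != cfg$cov_dim)
    stop("expected ", cfg$cov_dim, " covariate value(s)")
  out
}

default_tracker <- function(model) {
  bin_tracker(model$cfg$bin_centres, model$cfg$grid %/% 2L, model$cfg$lambda)
}

#' Stage-1 forward pass: covariate to conditional velocity field
#'
#' With `sample = FALSE` (the deterministic path used for template export)
#' the latent mean is decoded; with `sample = TRUE` the latent is drawn by
#' reparameterisation, seeded through R's RNG.
#'
#' @param model a `ct_model`.
#' @param alpha covariate (age, optionally followed by sex as +/-1).
#' @param sample draw the latent stochastically?
#' @param seed optional seed applied before the latent draw.
#' @return a `vector_field` (velocity) on the full model grid.
#' @export
stage1_forward <- function(model, alpha, sample = FALSE, seed = NULL) {
  cfg <- model$cfg
  if (!is.null(seed)) set.seed(seed)
  eps <- if (sample) stats::rnorm(cfg$latent) else numeric(cfg$latent)
  h <- cfg$grid %/% 2L
  zero <- numeric(2 * prod(h))
  r <- ca_model_run_cpp(engine_cfg(cfg), model$params, numeric(0),
                        matrix(0, cfg$grid[1], cfg$grid[2]), NULL,
                        normalize_covariate(cfg, alpha), eps, sample,
                        zero, zero, 0, 0, cfg$lambda, FALSE, FALSE,
                        cfg$gammas, FALSE, FALSE, TRUE)
  vhalf <- vector_field(array(r$v1h, c(h, 2L)), role = "velocity")
  upsample_field(vhalf)
}

#' Stage-2 forward pass: (conditional template, scan) to velocity field
#'
#' Deterministic given weights and inputs. Both images must be on the model
#' grid and share a common intensity range.
#'
#' @param model a `ct_model`.
#' @param T_alpha conditional template (`image_grid`).
#' @param X participant scan (`image_grid`).
#' @return a `vector_field` (velocity) on the full model grid.
#' @export
stage2_forward <- function(model, T_alpha, X) {
  cfg <- model$cfg
  check_same_grid(T_alpha, X, "template and scan")
  if (any(dim(T_alpha$data) != cfg$grid))
    stop("images are not on the model grid")
  h <- cfg$grid %/% 2L
  zero <- numeric(2 * prod(h))
  r <- ca_model_run_cpp(engine_cfg(cfg), model$params, numeric(0),
                        as_matrix2(T_alpha), as_matrix2(X),
                        normalize_covariate(cfg, cfg$cov_bounds[1]),
                        numeric(cfg$latent), FALSE,
                        zero, zero, 0, 0, cfg$lambda, FALSE, FALSE,
                        cfg$gammas, FALSE, FALSE, FALSE)
  vhalf <- vector_field(array(r$v2h, c(h, 2L)), role = "velocity")
  upsample_field(vhalf)
}

as_matrix2 <- function(img) {
  d <- dim(img$data)
  if (length(d) != 2L) stop("the network engine operates on 2-D images")
  matrix(img$data, d[1], d[2])
}

#' Build conditional templates for a list of conditioning values
#'
#' For each requested value the Stage-1 velocity is computed
#' deterministically, combined with the tracked per-bin means, both
#' velocities are integrated, and the group template is warped to give the
#' conditional template and its mean-adjusted counterpart. Values outside the
#' tracker range are clamped to the edge bin with a warning.
#'
#' @param model a trained `ct_model`.
#' @param tracker the `bin_tracker` trained alongside the model.
#' @param group_template the group template `image_grid`.
#' @param alphas conditioning values (ages).
#' @return a list with one entry per alpha, each holding `alpha`,
#'   `template` (T_alpha), `template_adj` (mean-adjusted T_alpha-hat),
#'   `phi` and `phi_adj` (full-grid deformations).
#' @export
build_templates <- function(model, tracker, group_template, alphas) {
  cfg <- model$cfg
  if (any(dim(group_template$data) != cfg$grid))
    stop("group template is not on the model grid")
  rng <- range(tracker$centres)
  if (any(alphas < rng[1] | alphas > rng[2]))
    warning("some conditioning values fall outside the tracker range; ",
            "clamping to the edge bins")
  lapply(alphas, function(a) {
    pr <- tracker_pair(tracker, a)
    r <- ca_model_run_cpp(engine_cfg(cfg), model$params, numeric(0),
                          as_matrix2(group_template), NULL,
                          normalize_covariate(cfg, a), numeric(cfg$latent),
                          FALSE,
                          as.numeric(tracker$means[[pr$k[1]]]),
                          as.numeric(tracker$means[[pr$k[2]]]),
                          pr$z[1], pr$z[2], cfg$lambda, FALSE, FALSE,
                          cfg$gammas, cfg$mean_loss == "l1", FALSE, TRUE)
    g <- cfg$grid
    list(alpha = a,
         template = image_grid(array(r$Talpha, g),
                               spacing = group_template$spacing,
                               affine = group_template$affine),
         template_adj = image_grid(array(r$That, g),
                                   spacing = group_template$spacing,
                                   affine = group_template$affine),
         phi = vector_field(array(r$u1f, c(g, 2L)), role = "deformation"),
         phi_adj = vector_field(array(r$uhatf, c(g, 2L)), role = "deformation"))
  })
}
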