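#' Bending energy of a deformation
#'
#' Mean, over interior voxels, of the squared Laplacian of the displacement
#' field summed over vector components, with the Laplacian taken by central
#' second differences. Border voxels are excluded (one-sided second
#' differences are noisy). The penalty is computed on the displacement
#' `u` rather than the full map `phi = x + u`; the two are identical because
#' the Laplacian of the identity map vanishes. Any affine field (translation,
#' rotation, scaling) has zero bending energy, so the penalty controls
#' curvature without opposing global size changes.
#'
#' @param phi a `vector_field` (role `"deformation"`).
#' @return non-negative scalar.
#' @export
bending_energy <- function(phi) {
  if (!inherits(phi, "vector_field")) stop("expected a vector_field")
  grid <- field_grid_dim(phi)
  if (any(grid < 3)) stop("grid too small for second differences")
  ca_bending_cpp(as.numeric(phi$data), as.integer(grid))
}

#' Mean squared displacement magnitude
#'
#' Mean over all voxels of the squared Euclidean norm of the displacement,
#' in voxel units.
#'
#' @param phi a `vector_field` (role `"deformation"`).
#' @return non-negative scalar.
#' @export
displacement_magnitude <- function(phi) {
  if (!inherits(phi, "vector_field")) stop("expected a vector_field")
  d <- dim(phi$data)
  nd <- length(d) - 1L
  sum(phi$data^2) / prod(d[seq_len(nd)])
}

#' Mean squared reconstruction error between two images
#'
#' @param pred,target `image_grid`s on the same grid.
#' @return non-negative scalar.
#' @export
recon_mse <- function(pred, target) {
  check_same_grid(pred, target, "images")
  mean((pred$data - target$data)^2)
}

#' Mean-consistency loss between conditional templates
#'
#' Penalty between a conditional template and its mean-adjusted counterpart
#' (the template rebuilt after adding the tracked local mean of Stage-2
#' velocities). Driving the two together keeps conditional templates centred
#' with respect to the deformations that map them to individual scans.
#' The default is a mean squared difference; an L1 (mean absolute difference)
#' variant is available.
#'
#' @param T_alpha,T_alpha_hat `image_grid`s on the same grid.
#' @param type `"mse"` (default) or `"l1"`.
#' @return non-negative scalar.
#' @export
mean_consistency_loss <- function(T_alpha, T_alpha_hat, type = c("mse", "l1")) {
  type <- match.arg(type)
  check_same_grid(T_alpha, T_alpha_hat, "templates")
  d <- T_alpha$data - T_alpha_hat$data
  if (type == "mse") mean(d^2) else mean(abs(d))
}

#' Bundle of the six training-loss components
#'
#' @param recon,bend1,bend2,disp1,disp2,mean non-negative component values.
#' @param weights the six non-negative weights, in the same order; defaults to
#'   the model's standard weighting (1, 0.01, 0.01, 0.01, 0.01, 1).
#' @return a `loss_bundle` with the components, weights, and weighted `total`.
#' @export
loss_bundle <- function(recon = 0, bend1 = 0, bend2 = 0, disp1 = 0, disp2 = 0,
                        mean = 0,
                        weights = c(1, 0.01, 0.01, 0.01, 0.01, 1)) {
  comp <- c(recon = recon, bend1 = bend1, bend2 = bend2,
            disp1 = disp1, disp2 = disp2, mean = mean)
  if (any(!is.finite(comp)) || any(comp < 0))
    stop("loss components must be finite and non-negative")
  if (length(weights) != 6 || any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be six finite non-negative values")
  structure(list(components = comp, weights = as.numeric(weights),
                 total = sum(comp * weights)),
            class = "loss_bundle")
}

#' Weighted total loss
#'
#' The gamma-weighted sum of the six components; linear in every component
#' and every weight.
#'
#' @param bundle a `loss_bundle`.
#' @return scalar total.
#' @export
total_loss <- function(bundle) {
  if (!inherits(bundle, "loss_bundle")) stop("expected a loss_bundle")
  sum(bundle$components * bundle$weights)
}

#' @export
print.loss_bundle <- function(x, ...) {
  cat("<loss_bundle> total ", signif(x$total, 6), "\n", sep = "")
  print(signif(x$components, 6))
  invisible(x)
}
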