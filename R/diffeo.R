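#' Integrate a stationary velocity field by scaling and squaring
#'
#' Computes the unit-time flow of the stationary ODE
#' \eqn{\partial\phi(x,t)/\partial t = v(\phi(x,t))}, i.e. the deformation
#' \eqn{\phi(x, 1)}, by the scaling-and-squaring scheme: the field is scaled to
#' a small Euler step \eqn{u_0 = v / 2^{steps}} and the resulting map is
#' composed with itself `steps` times. For smooth velocities of moderate
#' magnitude the result is diffeomorphic (strictly positive Jacobian
#' determinants).
#'
#' @param v a `vector_field` with role `"velocity"`.
#' @param steps number of squaring operations (default 7).
#' @return a `vector_field` with role `"deformation"` holding the displacement
#'   from identity in voxel units.
#' @export
integrate_svf <- function(v, steps = 7L) {
  expect_role(v, "velocity")
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be a positive integer")
  if (!all(is.finite(v$data))) stop("velocity field contains non-finite values")
  grid <- field_grid_dim(v)
  u <- ca_integrate_cpp(as.numeric(v$data), as.integer(grid), steps)
  vector_field(array(u, dim(v$data)), role = "deformation", spacing = v$spacing)
}

#' Warp an image through a deformation
#'
#' `out(x) = img(phi(x)) = img(x + u(x))`. Linear mode uses bilinear
#' (2-D) / trilinear (3-D) interpolation; nearest mode is for label maps.
#' Out-of-bounds samples clamp to the border voxel by default (avoiding a
#' zero halo around warped templates); set `padding = "zero"` for zero
#' padding.
#'
#' @param img an `image_grid`.
#' @param phi a `vector_field` with role `"deformation"` on the same grid.
#' @param mode `"linear"` or `"nearest"`.
#' @param padding `"clamp"` (default) or `"zero"`.
#' @return the warped `image_grid`.
#' @export
warp <- function(img, phi, mode = c("linear", "nearest"),
                 padding = c("clamp", "zero")) {
  mode <- match.arg(mode)
  padding <- match.arg(padding)
  if (!inherits(img, "image_grid")) stop("img must be an image_grid")
  expect_role(phi, "deformation")
  check_same_grid(img, phi, "image and deformation")
  grid <- dim(img$data)
  out <- ca_warp_cpp(as.numeric(img$data), as.numeric(phi$data),
                     as.integer(grid), 1L, mode == "nearest", padding == "zero")
  image_grid(array(out, grid), spacing = img$spacing, affine = img$affine)
}

#' Compose two deformations
#'
#' Returns the deformation whose map is \eqn{\phi_{outer} \circ \phi_{inner}},
#' i.e. `result(x) = phi_outer(phi_inner(x))`. In displacement form,
#' `u(x) = u_inner(x) + u_outer(x + u_inner(x))`, with the outer displacement
#' resampled by linear interpolation (border clamped).
#'
#' @param phi_outer,phi_inner `vector_field`s with role `"deformation"` on the
#'   same grid.
#' @return the composed deformation.
#' @export
compose <- function(phi_outer, phi_inner) {
  expect_role(phi_outer, "deformation")
  expect_role(phi_inner, "deformation")
  check_same_grid(phi_outer, phi_inner, "deformations")
  grid <- field_grid_dim(phi_inner)
  nd <- length(grid)
  sampled <- ca_warp_cpp(as.numeric(phi_outer$data), as.numeric(phi_inner$data),
                         as.integer(grid), as.integer(nd), FALSE, FALSE)
  vector_field(array(as.numeric(phi_inner$data) + sampled, dim(phi_inner$data)),
               role = "deformation", spacing = phi_inner$spacing)
}

#' Voxel-wise Jacobian determinant of a deformation
#'
#' The Jacobian of the full map \eqn{\phi = x + u} is \eqn{I + \nabla u};
#' gradients use central differences at interior voxels and one-sided
#' differences at borders. Values less than or equal to zero indicate local
#' topology violation (folding); the identity deformation yields 1 everywhere.
#'
#' @param phi a `vector_field` with role `"deformation"`.
#' @return an `image_grid` of determinant values.
#' @export
jacobian_determinant <- function(phi) {
  expect_role(phi, "deformation")
  grid <- field_grid_dim(phi)
  if (any(grid < 3)) stop("grid must have at least 3 voxels per axis")
  det <- ca_jacdet_cpp(as.numeric(phi$data), as.integer(grid))
  image_grid(array(det, grid), spacing = phi$spacing)
}

#' Bilinearly upsample a field from half resolution to a full grid
#'
#' The model predicts velocities at half the image resolution; this helper
#' doubles the grid and rescales the vector components to full-grid voxel
#' units (a displacement of one half-grid voxel is two full-grid voxels).
#'
#' @param field a `vector_field` on a 2-D grid.
#' @return a `vector_field` on the doubled grid.
#' @keywords internal
upsample_field <- function(field) {
  d <- dim(field$data)
  nd <- length(d) - 1L
  if (nd != 2L) stop("upsample_field supports 2-D fields")
  n1 <- d[1]; n2 <- d[2]
  m1 <- 2L * n1; m2 <- 2L * n2
  taps <- function(m, n) {
    p <- pmin(pmax((seq_len(m) - 1 - 0.5) / 2, 0), n - 1)
    i0 <- pmin(floor(p), n - 2)
    list(i0 = i0 + 1L, f = p - i0)
  }
  t1 <- taps(m1, n1); t2 <- taps(m2, n2)
  out <- array(0, c(m1, m2, nd))
  for (c in seq_len(nd)) {
    s <- field$data[, , c]
    a00 <- s[t1$i0, t2$i0]; a10 <- s[t1$i0 + 1L, t2$i0]
    a01 <- s[t1$i0, t2$i0 + 1L]; a11 <- s[t1$i0 + 1L, t2$i0 + 1L]
    f1 <- matrix(t1$f, m1, m2); f2 <- matrix(t2$f, m1, m2, byrow = TRUE)
    out[, , c] <- 2 * ((1 - f1) * (1 - f2) * a00 + f1 * (1 - f2) * a10 +
                       (1 - f1) * f2 * a01 + f1 * f2 * a11)
  }
  vector_field(out, role = field$role, spacing = field$spacing / 2)
}
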