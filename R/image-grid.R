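#' Scalar image on a voxel grid
#'
#' `image_grid` is the container for every image handled by the package: the
#' group template, conditional templates, participant scans and label maps.
#' Intensities live on a 2-D or 3-D voxel grid; the voxel size and a
#' voxel-to-world affine are carried as metadata only -- all modelling and
#' evaluation operate in voxel space, on the assumption that inputs have been
#' affinely aligned beforehand.
#'
#' @param data numeric matrix (2-D) or 3-D array of finite intensities.
#' @param spacing per-axis voxel size in mm (strictly positive).
#' @param affine 4x4 voxel-to-world transform; identity if omitted.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(data, spacing = rep(1, length(dim(data))), affine = diag(4)) {
  data <- as_grid_array(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stop("image_grid data must be 2-D or 3-D")
  if (!all(is.finite(data))) stop("image_grid intensities must all be finite")
  if (length(spacing) != nd || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be ", nd, " strictly positive values")
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4)))
    stop("affine must be a 4x4 matrix")
  structure(list(data = data, spacing = as.numeric(spacing), affine = affine),
            class = "image_grid")
}

as_grid_array <- function(data) {
  if (is.null(dim(data))) stop("data must carry dimensions")
  storage.mode(data) <- "double"
  data
}

#' @export
print.image_grid <- function(x, ...) {
  cat("<image_grid> ", paste(dim(x$data), collapse = " x "),
      " | spacing ", paste(signif(x$spacing, 4), collapse = " x "), " mm",
      " | range [", signif(min(x$data), 4), ", ", signif(max(x$data), 4), "]\n",
      sep = "")
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$data)

#' Per-voxel vector field (velocity or deformation)
#'
#' Stationary velocity fields and deformation fields share one container.
#' A deformation-role field stores the displacement from identity `u`, in
#' voxel units, so that the map is `phi(x) = x + u(x)`. The array has one
#' trailing dimension holding the vector components, whose count equals the
#' spatial dimensionality.
#'
#' @param data array of dimension `c(grid, d)` where `d` is 2 or 3 and equals
#'   the number of grid dimensions.
#' @param role `"velocity"` or `"deformation"`.
#' @param spacing per-axis voxel size in mm (metadata only).
#' @return an object of class `vector_field`.
#' @export
vector_field <- function(data, role = c("velocity", "deformation"),
                         spacing = rep(1, length(dim(data)) - 1L)) {
  role <- match.arg(role)
  data <- as_grid_array(data)
  nd <- length(dim(data)) - 1L
  if (!nd %in% c(2L, 3L)) stop("vector_field must be on a 2-D or 3-D grid")
  d <- dim(data)[nd + 1L]
  if (d != nd)
    stop("vector dimensionality (", d, ") must equal spatial dimensionality (", nd, ")")
  if (!all(is.finite(data))) stop("vector_field components must all be finite")
  structure(list(data = data, role = role, spacing = as.numeric(spacing)),
            class = "vector_field")
}

#' @export
print.vector_field <- function(x, ...) {
  nd <- length(dim(x$data)) - 1L
  cat("<vector_field:", x$role, "> grid ",
      paste(dim(x$data)[seq_len(nd)], collapse = " x "),
      " | max |comp| ", signif(max(abs(x$data)), 4), "\n", sep = "")
  invisible(x)
}

field_grid_dim <- function(field) {
  d <- dim(field$data)
  d[-length(d)]
}

#' Identity deformation on a grid
#'
#' @param grid integer grid dimensions (length 2 or 3).
#' @return a `vector_field` of role `"deformation"` with zero displacement.
#' @export
identity_deformation <- function(grid) {
  vector_field(array(0, c(grid, length(grid))), role = "deformation")
}

check_same_grid <- function(a, b, what = "inputs") {
  da <- if (inherits(a, "image_grid")) dim(a$data) else field_grid_dim(a)
  db <- if (inherits(b, "image_grid")) dim(b$data) else field_grid_dim(b)
  if (length(da) != length(db) || any(da != db))
    stop(what, " are on different grids: ", paste(da, collapse = "x"), " vs ",
         paste(db, collapse = "x"))
  invisible(TRUE)
}

expect_role <- function(field, role) {
  if (!inherits(field, "vector_field")) stop("expected a vector_field")
  if (field$role != role)
    stop("expected a ", role, "-role field, got ", field$role)
  invisible(TRUE)
}
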