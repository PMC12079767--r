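# Shared fixtures: smooth analytic velocity fields and small images, built in
# code so that expected values derive from closed forms.

# Smooth random velocity field from low-frequency sinusoids, rescaled so the
# largest component magnitude equals max_mag voxels. Works in 2-D and 3-D.
smooth_velocity <- function(grid, max_mag = 2, seed = 1) {
  set.seed(seed)
  nd <- length(grid)
  coords <- lapply(grid, function(n) (seq_len(n) - 1) / (n - 1)) # in [0,1]
  mesh <- function(k) {
    a <- array(0, grid)
    idx <- slice.index(a, k)
    array(coords[[k]][idx], grid)
  }
  xs <- lapply(seq_len(nd), mesh)
  out <- array(0, c(grid, nd))
  for (c in seq_len(nd)) {
    f <- array(0, grid)
    for (t in 1:3) {
      w <- stats::runif(nd, 0.5, 1.5) * pi
      ph <- stats::runif(nd, 0, 2 * pi)
      amp <- stats::rnorm(1)
      term <- amp
      for (k in seq_len(nd)) term <- term * sin(w[k] * xs[[k]] + ph[k])
      f <- f + term
    }
    if (nd == 2) out[, , c] <- f else out[, , , c] <- f
  }
  out <- out * (max_mag / max(abs(out)))
  vector_field(out, role = "velocity")
}

# Linear velocity field v(x) = A (x - x0), as a vector_field.
linear_velocity <- function(grid, A, x0) {
  nd <- length(grid)
  pts <- as.matrix(expand.grid(lapply(grid, function(n) seq_len(n) - 1)))
  v <- t(A %*% t(sweep(pts, 2, x0)))
  vector_field(array(v, c(grid, nd)), role = "velocity")
}

# Displacement of the exact flow of the linear field, via matrix exponential.
linear_flow_displacement <- function(grid, A, x0) {
  nd <- length(grid)
  E <- as.matrix(Matrix::expm(A))
  pts <- as.matrix(expand.grid(lapply(grid, function(n) seq_len(n) - 1)))
  u <- t((E - diag(nd)) %*% t(sweep(pts, 2, x0)))
  vector_field(array(u, c(grid, nd)), role = "deformation")
}

# Interior index list with the given margin (returns an array index mask).
interior_mask <- function(grid, margin) {
  m <- array(TRUE, grid)
  for (k in seq_along(grid)) {
    idx <- slice.index(m, k)
    m <- m & idx > margin & idx <= grid[k] - margin
  }
  m
}

# Tiny network configuration used by gradient and trainer tests.
tiny_config <- function(...) {
  ct_config(grid = c(16L, 16L), latent = 4L, s1_hidden = 8L, s1_ch0 = 8L,
            s1_g0 = 4L, s1_up_ch = 6L, s2_ch = c(4L, 6L, 6L, 6L),
            cov_bounds = c(50, 90), bin_centres = seq(50, 90, 10), ...)
}

# Small phantom spec on the tiny grid.
tiny_spec <- function(...) phantom_spec(grid = c(16L, 16L), ...)
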