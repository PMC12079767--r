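# Stationary-velocity-field integration, warping, composition, Jacobians.

test_that("integrating the zero field gives the exact identity", {
  v <- vector_field(array(0, c(12, 10, 2)), role = "velocity")
  u <- integrate_svf(v)
  expect_identical(as.numeric(u$data), rep(0, 240))
  expect_equal(u$role, "deformation")

  v3 <- vector_field(array(0, c(6, 6, 6, 3)), role = "velocity")
  expect_identical(as.numeric(integrate_svf(v3)$data), rep(0, 6^3 * 3))
})

test_that("a constant velocity integrates to the same constant translation", {
  v <- array(0, c(16, 16, 2)); v[, , 1] <- 1.3; v[, , 2] <- -0.7
  u <- integrate_svf(vector_field(v, role = "velocity"))
  expect_equal(max(abs(u$data[, , 1] - 1.3)), 0, tolerance = 1e-12)
  expect_equal(max(abs(u$data[, , 2] + 0.7)), 0, tolerance = 1e-12)

  v3 <- array(0, c(8, 8, 8, 3)); v3[, , , 2] <- 0.9
  u3 <- integrate_svf(vector_field(v3, role = "velocity"))
  expect_equal(max(abs(u3$data[, , , 2] - 0.9)), 0, tolerance = 1e-12)
})

test_that("linear-field integration matches the matrix-exponential flow", {
  # The relative truncation of scaling-and-squaring on the displacement is
  # about ||A|| / 2^(s+1); ten squarings give a comfortable margin below 1e-3
  # at ||A|| = 0.5.
  grid <- c(32L, 32L)
  x0 <- c(15.5, 15.5)
  set.seed(11)
  for (rep in 1:3) {
    A <- matrix(stats::rnorm(4, sd = 0.2), 2, 2)
    A <- A * (0.5 / max(svd(A)$d)) # exactly norm 0.5
    u <- integrate_svf(linear_velocity(grid, A, x0), steps = 10L)
    utrue <- linear_flow_displacement(grid, A, x0)
    keep <- interior_mask(grid, 10)
    err <- 0
    for (c in 1:2) err <- max(err, max(abs((u$data[, , c] - utrue$data[, , c])[keep])))
    scale <- max(abs(utrue$data[rep(keep, 2)]))
    expect_lt(err / scale, 1e-3)
  }

  # 3-D
  grid3 <- c(16L, 16L, 16L)
  x03 <- c(7.5, 7.5, 7.5)
  A3 <- matrix(c(0, -0.3, 0.05, 0.3, 0, 0, 0, 0.05, -0.1), 3, 3)
  A3 <- A3 * (0.5 / max(svd(A3)$d))
  u3 <- integrate_svf(linear_velocity(grid3, A3, x03), steps = 10L)
  utrue3 <- linear_flow_displacement(grid3, A3, x03)
  keep3 <- interior_mask(grid3, 5)
  err3 <- max(abs(array(u3$data - utrue3$data, c(grid3, 3))[rep(keep3, 3)]))
  scale3 <- max(abs(utrue3$data[rep(keep3, 3)]))
  expect_lt(err3 / scale3, 1e-3)
})

test_that("scaling-and-squaring error shrinks as steps grow", {
  grid <- c(32L, 32L)
  x0 <- c(15.5, 15.5)
  A <- matrix(c(0, -0.4, 0.4, 0.1), 2, 2)
  A <- A * (0.5 / max(svd(A)$d))
  utrue <- linear_flow_displacement(grid, A, x0)
  keep <- rep(interior_mask(grid, 10), 2)
  err_at <- function(s) {
    u <- integrate_svf(linear_velocity(grid, A, x0), steps = s)
    max(abs((u$data - utrue$data)[keep]))
  }
  expect_lt(err_at(7), err_at(3))
})

test_that("flows of v and -v are inverse to each other", {
  for (seed in 1:3) {
    v <- smooth_velocity(c(32L, 32L), max_mag = 2, seed = seed)
    fwd <- integrate_svf(v)
    bwd <- integrate_svf(vector_field(-v$data, role = "velocity"))
    comp <- compose(fwd, bwd)
    keep <- rep(interior_mask(c(32L, 32L), 4), 2)
    expect_lt(max(abs(comp$data[keep])), 0.1)
  }
})

test_that("warping is exact for identity, lattice shifts and linear ramps", {
  set.seed(2)
  img <- image_grid(matrix(stats::runif(16 * 16), 16, 16))
  id <- identity_deformation(c(16L, 16L))
  expect_identical(warp(img, id)$data, img$data)

  shift <- array(0, c(16, 16, 2)); shift[, , 1] <- 1
  w <- warp(img, vector_field(shift, role = "deformation"))
  expect_equal(w$data[1:15, ], img$data[2:16, ], tolerance = 1e-14)

  ramp <- image_grid(matrix(rep(0:15, 16), 16, 16)) # value = x1 coordinate
  half <- array(0, c(16, 16, 2)); half[, , 1] <- 0.5
  wr <- warp(ramp, vector_field(half, role = "deformation"))
  expect_equal(wr$data[2:14, ], ramp$data[2:14, ] + 0.5, tolerance = 1e-12)
})

test_that("warp is linear in image intensities and supports nearest mode", {
  set.seed(3)
  a <- matrix(stats::runif(256), 16, 16)
  b <- matrix(stats::runif(256), 16, 16)
  phi <- integrate_svf(smooth_velocity(c(16L, 16L), max_mag = 1.5, seed = 9))
  wa <- warp(image_grid(a), phi)$data
  wb <- warp(image_grid(b), phi)$data
  wab <- warp(image_grid(2 * a + 3 * b), phi)$data
  expect_equal(wab, 2 * wa + 3 * wb, tolerance = 1e-12)

  labs <- image_grid(matrix(sample(0:3, 256, TRUE), 16, 16))
  wl <- warp(labs, phi, mode = "nearest")
  expect_true(all(wl$data %in% 0:3))
})

test_that("composition is associative with identity and adds translations", {
  phi <- integrate_svf(smooth_velocity(c(16L, 16L), max_mag = 1, seed = 5))
  id <- identity_deformation(c(16L, 16L))
  expect_equal(compose(id, phi)$data, phi$data, tolerance = 1e-12)
  keep <- rep(interior_mask(c(16L, 16L), 3), 2)
  expect_lt(max(abs((compose(phi, id)$data - phi$data)[keep])), 1e-12)

  ta <- array(0, c(16, 16, 2)); ta[, , 1] <- 0.7; ta[, , 2] <- -0.3
  tb <- array(0, c(16, 16, 2)); tb[, , 1] <- -0.2; tb[, , 2] <- 0.9
  comp <- compose(vector_field(ta, role = "deformation"),
                  vector_field(tb, role = "deformation"))
  expect_equal(comp$data[4:12, 4:12, 1], matrix(0.5, 9, 9), tolerance = 1e-12)
  expect_equal(comp$data[4:12, 4:12, 2], matrix(0.6, 9, 9), tolerance = 1e-12)
})

test_that("Jacobian determinants: identity, uniform scaling, brute-force oracle", {
  id <- identity_deformation(c(12L, 12L))
  expect_equal(as.numeric(jacobian_determinant(id)$data), rep(1, 144))

  # uniform scaling by s about the grid centre: phi(x) = c + s (x - c)
  for (grid in list(c(16L, 16L), c(10L, 10L, 10L))) {
    s <- 1.1
    nd <- length(grid)
    ctr <- (grid - 1) / 2
    pts <- as.matrix(expand.grid(lapply(grid, function(n) seq_len(n) - 1)))
    u <- (s - 1) * sweep(pts, 2, ctr)
    phi <- vector_field(array(u, c(grid, nd)), role = "deformation")
    jd <- jacobian_determinant(phi)$data
    keep <- interior_mask(grid, 1)
    expect_lt(max(abs(jd[keep] - s^nd)), 1e-6)
  }

  # independent R oracle: central differences and 2x2 determinant per voxel
  phi <- integrate_svf(smooth_velocity(c(20L, 20L), max_mag = 2, seed = 7))
  jd <- jacobian_determinant(phi)$data
  u <- phi$data
  oracle <- matrix(NA_real_, 20, 20)
  for (i in 2:19) for (j in 2:19) {
    d11 <- 1 + (u[i + 1, j, 1] - u[i - 1, j, 1]) / 2
    d12 <- (u[i, j + 1, 1] - u[i, j - 1, 1]) / 2
    d21 <- (u[i + 1, j, 2] - u[i - 1, j, 2]) / 2
    d22 <- 1 + (u[i, j + 1, 2] - u[i, j - 1, 2]) / 2
    oracle[i, j] <- d11 * d22 - d12 * d21
  }
  expect_lt(max(abs(jd[2:19, 2:19] - oracle[2:19, 2:19])), 1e-10)
})

test_that("smooth SVF flows stay diffeomorphic (positive determinants)", {
  for (seed in 1:4) {
    phi <- integrate_svf(smooth_velocity(c(24L, 24L), max_mag = 2, seed = seed))
    jd <- jacobian_determinant(phi)$data
    keep <- interior_mask(c(24L, 24L), 1)
    expect_gt(min(jd[keep]), 0)
  }
})

test_that("invalid geometric inputs are rejected with diagnostics", {
  v <- vector_field(array(0, c(8, 8, 2)), role = "velocity")
  expect_error(integrate_svf(v, steps = 0), "positive")
  bad <- v; bad$data[1] <- NA
  expect_error(integrate_svf(bad), "finite")
  img <- image_grid(matrix(0, 8, 8))
  phi10 <- identity_deformation(c(10L, 10L))
  expect_error(warp(img, phi10), "different grids")
  expect_error(compose(phi10, identity_deformation(c(8L, 8L))), "different grids")
  expect_error(warp(img, v), "deformation")
})
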