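# The six loss components and their weighted total.

test_that("bending energy vanishes on affine fields", {
  grid <- c(16L, 16L)
  pts <- as.matrix(expand.grid(x = 0:15, y = 0:15))
  # translation + rotation + anisotropic scaling
  th <- 0.3
  M <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*% diag(c(1.2, 0.8))
  u <- t(M %*% t(sweep(pts, 2, c(7.5, 7.5)))) - sweep(pts, 2, c(7.5, 7.5)) + 2.5
  phi <- vector_field(array(u, c(grid, 2)), role = "deformation")
  expect_lt(bending_energy(phi), 1e-10)
  expect_identical(bending_energy(identity_deformation(grid)), 0)
})

test_that("bending energy of a quadratic displacement matches the closed form", {
  # u1(x) = x1^2 has discrete Laplacian exactly 2, so the energy is 4
  grid <- c(9L, 9L)
  u <- array(0, c(grid, 2))
  u[, , 1] <- matrix((0:8)^2, 9, 9)
  expect_equal(bending_energy(vector_field(u, role = "deformation")), 4,
               tolerance = 1e-12)
})

test_that("bending energy is invariant to adding an affine field", {
  set.seed(4)
  phi <- integrate_svf(smooth_velocity(c(16L, 16L), max_mag = 2, seed = 21))
  e0 <- bending_energy(phi)
  aff <- array(0, c(16, 16, 2))
  aff[, , 1] <- outer(0:15, rep(1, 16)) * 0.05 + 1 # linear in x1 + shift
  aff[, , 2] <- outer(rep(1, 16), 0:15) * -0.03
  shifted <- vector_field(phi$data + aff, role = "deformation")
  expect_equal(bending_energy(shifted), e0, tolerance = 1e-10)
})

test_that("displacement magnitude averages the squared norm over voxels", {
  expect_identical(displacement_magnitude(identity_deformation(c(8L, 8L))), 0)
  tr <- array(0, c(8, 8, 2)); tr[, , 1] <- 1
  expect_equal(displacement_magnitude(vector_field(tr, role = "deformation")), 1)
  set.seed(5)
  u <- array(stats::rnorm(8 * 8 * 2), c(8, 8, 2))
  oracle <- sum(u[, , 1]^2 + u[, , 2]^2) / 64 # brute-force per-voxel sum
  expect_equal(displacement_magnitude(vector_field(u, role = "deformation")),
               oracle, tolerance = 1e-12)
})

test_that("reconstruction and mean-consistency losses match brute force", {
  set.seed(6)
  a <- image_grid(matrix(stats::runif(100), 10, 10))
  b <- image_grid(matrix(stats::runif(100), 10, 10))
  expect_identical(recon_mse(a, a), 0)
  ac <- image_grid(a$data + 0.3)
  expect_equal(recon_mse(ac, a), 0.09, tolerance = 1e-12)
  expect_equal(recon_mse(a, b), mean((a$data - b$data)^2), tolerance = 1e-14)

  expect_identical(mean_consistency_loss(a, a), 0)
  expect_equal(mean_consistency_loss(ac, a), 0.09, tolerance = 1e-12)
  expect_equal(mean_consistency_loss(a, b, type = "l1"),
               mean(abs(a$data - b$data)), tolerance = 1e-14)
  expect_error(recon_mse(a, image_grid(matrix(0, 9, 9))), "different grids")
})

test_that("the weighted total combines six components with the standard weights", {
  expect_equal(total_loss(loss_bundle()), 0)
  unit <- loss_bundle(1, 1, 1, 1, 1, 1)
  expect_equal(total_loss(unit), 2.04, tolerance = 1e-12)
  only_recon <- loss_bundle(recon = 0.37, weights = c(1, 0, 0, 0, 0, 0))
  expect_equal(total_loss(only_recon), 0.37)
  expect_error(loss_bundle(1, weights = c(-1, 0, 0, 0, 0, 0)), "non-negative")
  expect_error(loss_bundle(recon = -0.1), "non-negative")
})

test_that("the total is linear in components and weights", {
  set.seed(7)
  comp <- stats::runif(6)
  w <- stats::runif(6)
  b1 <- do.call(loss_bundle, c(as.list(comp), list(weights = w)))
  b2 <- do.call(loss_bundle, c(as.list(2 * comp), list(weights = w)))
  expect_equal(total_loss(b2), 2 * total_loss(b1), tolerance = 1e-12)
  b3 <- do.call(loss_bundle, c(as.list(comp), list(weights = 3 * w)))
  expect_equal(total_loss(b3), 3 * total_loss(b1), tolerance = 1e-12)
})
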