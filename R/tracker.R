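#' Soft-binned tracker of local mean Stage-2 velocities
#'
#' The conditioning axis (age) is divided into bins; each bin stores a running
#' mean velocity field updated by an exponential moving average during
#' training. A sample's update is apportioned to its two nearest bins by
#' triangular weights, so every scan contributes fractionally to the local
#' means. Tracked means persist across batches (3-D batch sizes are too small
#' for a useful within-batch average) and are state, not learnable
#' parameters.
#'
#' @param centres strictly increasing bin centres (conditioning values, e.g.
#'   ages in years).
#' @param grid grid dimensions of the tracked velocity fields (the model's
#'   velocity resolution).
#' @param lambda global update rate in (0, 1); default 0.1.
#' @return an object of class `bin_tracker`.
#' @export
bin_tracker <- function(centres, grid, lambda = 0.1) {
  centres <- as.numeric(centres)
  if (length(centres) < 2 || any(diff(centres) <= 0))
    stop("centres must be at least two strictly increasing values")
  if (!is.finite(lambda) || lambda <= 0 || lambda >= 1)
    stop("lambda must lie in the open unit interval")
  grid <- as.integer(grid)
  d <- length(grid)
  means <- lapply(seq_along(centres), function(k) array(0, c(grid, d)))
  structure(list(centres = centres, grid = grid, lambda = lambda,
                 means = means),
            class = "bin_tracker")
}

#' @export
print.bin_tracker <- function(x, ...) {
  cat("<bin_tracker> ", length(x$centres), " bins over [",
      min(x$centres), ", ", max(x$centres), "], lambda ", x$lambda,
      ", grid ", paste(x$grid, collapse = "x"), "\n", sep = "")
  invisible(x)
}

#' Soft-binning weights for a conditioning value
#'
#' Triangular kernel: weight 1 at a bin's centre, falling linearly to 0 at the
#' neighbouring centres, 0 beyond. For a value between two adjacent centres
#' the two weights form a partition of unity. Values outside the covered
#' range clamp to the nearest edge bin (weight 1), avoiding extrapolation of
#' the tracked means.
#'
#' @param tracker a `bin_tracker`.
#' @param alpha conditioning value.
#' @return numeric vector of per-bin weights summing to 1.
#' @export
bin_weights <- function(tracker, alpha) {
  if (!is.finite(alpha)) stop("alpha must be finite")
  ct <- tracker$centres
  K <- length(ct)
  w <- numeric(K)
  if (alpha <= ct[1]) {
    w[1] <- 1
  } else if (alpha >= ct[K]) {
    w[K] <- 1
  } else {
    k <- findInterval(alpha, ct)
    t <- (alpha - ct[k]) / (ct[k + 1] - ct[k])
    w[k] <- 1 - t
    w[k + 1] <- t
  }
  w
}

#' Single-bin soft weight
#'
#' @param tracker a `bin_tracker`.
#' @param k bin index.
#' @param alpha conditioning value.
#' @return scalar in \[0, 1\].
#' @export
bin_weight <- function(tracker, k, alpha) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > length(tracker$centres))
    stop("invalid bin index")
  bin_weights(tracker, alpha)[k]
}

#' Update the tracked mean velocities with one sample
#'
#' For the (at most two) bins with non-zero soft weight, applies the
#' exponential moving average
#' \eqn{\bar v_k \leftarrow (1 - q_k)\,\bar v_k + q_k\, v} with
#' \eqn{q_k = \lambda\,\zeta_k(\alpha)}; other bins are unchanged. This is a
#' pure state update, excluded from gradient-based learning.
#'
#' @param tracker a `bin_tracker`.
#' @param v a `vector_field` (velocity) on the tracker grid.
#' @param alpha conditioning value of the sample.
#' @return the updated `bin_tracker`.
#' @export
update_mean <- function(tracker, v, alpha) {
  expect_role(v, "velocity")
  if (!all(field_grid_dim(v) == tracker$grid))
    stop("velocity field is not on the tracker grid")
  w <- bin_weights(tracker, alpha)
  for (k in which(w > 0)) {
    q <- tracker$lambda * w[k]
    tracker$means[[k]] <- (1 - q) * tracker$means[[k]] + q * v$data
  }
  tracker
}

#' Mean-adjusted conditional velocity
#'
#' Adds the soft-weighted tracked means of the two bracketing bins to a
#' Stage-1 conditional velocity:
#' \eqn{\hat v_\alpha = v_\alpha + \zeta_k(\alpha)\bar v_k +
#' \zeta_{k+1}(\alpha)\bar v_{k+1}}. The tracked means enter as constants.
#' With all tracked means zero this is the identity on `v_alpha`.
#'
#' @param tracker a `bin_tracker`.
#' @param v_alpha a `vector_field` (velocity) on the tracker grid.
#' @param alpha conditioning value.
#' @return the combined velocity `vector_field`.
#' @export
combine_velocity <- function(tracker, v_alpha, alpha) {
  expect_role(v_alpha, "velocity")
  if (!all(field_grid_dim(v_alpha) == tracker$grid))
    stop("velocity field is not on the tracker grid")
  w <- bin_weights(tracker, alpha)
  out <- v_alpha$data
  for (k in which(w > 0)) out <- out + w[k] * tracker$means[[k]]
  vector_field(out, role = "velocity", spacing = v_alpha$spacing)
}

# Two bracketing bins and their weights, as needed by the C++ engine.
tracker_pair <- function(tracker, alpha) {
  w <- bin_weights(tracker, alpha)
  nz <- which(w > 0)
  if (length(nz) == 1L) nz <- c(nz, if (nz < length(w)) nz + 1L else nz - 1L)
  list(k = nz[1:2], z = w[nz[1:2]])
}
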