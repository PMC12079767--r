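#' Jacobian-determinant topology report
#'
#' Summarises the voxel-wise Jacobian determinants of one or more deformation
#' fields: per-field and pooled min / max / mean / sd, the count of voxels
#' with non-positive determinant (topology violations), and a pooled
#' histogram. A foreground mask restricts the count of non-positive voxels
#' when supplied.
#'
#' @param phis list of `vector_field`s (role `"deformation"`).
#' @param mask optional logical array on the same grid.
#' @param breaks histogram breaks (passed to [hist()]).
#' @return `list(per_field = <data.frame>, pooled = <one-row data.frame>,
#'   histogram = <hist object>)`.
#' @export
jacobian_report <- function(phis, mask = NULL, breaks = 50) {
  if (!length(phis)) stop("empty list of deformations")
  if (inherits(phis, "vector_field")) phis <- list(phis)
  dets <- lapply(phis, function(p) jacobian_determinant(p)$data)
  summ <- function(d) {
    v <- if (is.null(mask)) as.numeric(d) else as.numeric(d[mask])
    data.frame(min = min(v), max = max(v), mean = mean(v), sd = stats::sd(v),
               n_nonpositive = sum(v <= 0))
  }
  per <- do.call(rbind, lapply(dets, summ))
  per$field <- seq_along(dets)
  pooled_vals <- unlist(lapply(dets, function(d)
    if (is.null(mask)) as.numeric(d) else as.numeric(d[mask])))
  pooled <- summ(array(pooled_vals, c(length(pooled_vals), 1)))
  list(per_field = per[, c("field", "min", "max", "mean", "sd", "n_nonpositive")],
       pooled = pooled,
       histogram = graphics::hist(pooled_vals, breaks = breaks, plot = FALSE))
}

gauss_kernel_op <- function(n, sigma, width) {
  half <- (width - 1) / 2
  k <- exp(-(-half:half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-half:half)
    idx <- pmin(pmax(idx, 1), n) # replicate padding at the borders
    for (t in seq_along(idx)) op[i, idx[t]] <- op[i, idx[t]] + k[t]
  }
  op
}

gauss_filter2 <- function(x, sigma, width) {
  g1 <- gauss_kernel_op(nrow(x), sigma, width)
  g2 <- gauss_kernel_op(ncol(x), sigma, width)
  g1 %*% x %*% t(g2)
}

#' Structural similarity index (SSIM)
#'
#' Windowed SSIM combining luminance, contrast and structure, with a Gaussian
#' window (sigma 1.5, width 11) and the standard stabilizing constants
#' `C1 = (K1 L)^2`, `C2 = (K2 L)^2` with `K = (0.01, 0.03)` and dynamic range
#' `L`. The SSIM map is averaged over the whole grid; the measure is
#' symmetric in its arguments and equals 1 for identical images.
#'
#' @param x,y `image_grid`s on the same grid.
#' @param dynamic_range intensity range `L` (default 1 for \[0, 1\] images).
#' @param sigma,window Gaussian window parameters.
#' @param K the two stabilizer fractions.
#' @return scalar in \[-1, 1\].
#' @export
ssim <- function(x, y, dynamic_range = 1, sigma = 1.5, window = 11,
                 K = c(0.01, 0.03)) {
  check_same_grid(x, y, "images")
  a <- x$data; b <- y$data
  if (length(dim(a)) != 2L) stop("ssim is implemented for 2-D images")
  C1 <- (K[1] * dynamic_range)^2
  C2 <- (K[2] * dynamic_range)^2
  mu_a <- gauss_filter2(a, sigma, window)
  mu_b <- gauss_filter2(b, sigma, window)
  va <- gauss_filter2(a * a, sigma, window) - mu_a^2
  vb <- gauss_filter2(b * b, sigma, window) - mu_b^2
  vab <- gauss_filter2(a * b, sigma, window) - mu_a * mu_b
  map <- ((2 * mu_a * mu_b + C1) * (2 * vab + C2)) /
         ((mu_a^2 + mu_b^2 + C1) * (va + vb + C2))
  mean(map)
}

#' Root mean squared intensity difference
#'
#' @param x,y `image_grid`s on the same grid.
#' @return non-negative scalar.
#' @export
rmsd <- function(x, y) {
  check_same_grid(x, y, "images")
  sqrt(mean((x$data - y$data)^2))
}

#' Dice similarity coefficient per label
#'
#' `2 |A intersect B| / (|A| + |B|)` for each requested label; `NA` when the
#' label is absent from both maps.
#'
#' @param a,b label `image_grid`s on the same grid (integer-valued).
#' @param labels labels to score; defaults to all non-zero labels present in
#'   either map.
#' @return named numeric vector of Dice scores.
#' @export
dice <- function(a, b, labels = NULL) {
  check_same_grid(a, b, "label maps")
  la <- round(a$data); lb <- round(b$data)
  if (is.null(labels)) {
    labels <- sort(unique(c(la[la != 0], lb[lb != 0])))
  }
  out <- vapply(labels, function(l) {
    na <- sum(la == l); nb <- sum(lb == l)
    if (na + nb == 0) return(NA_real_)
    2 * sum(la == l & lb == l) / (na + nb)
  }, numeric(1))
  names(out) <- labels
  out
}

#' Normalize volumes by their mean over the conditioning set
#'
#' Each volume is divided by the mean volume of the same ROI (and method)
#' across the whole conditioning set, so that the normalized values average
#' to exactly 1 per (method, ROI) -- the contract that makes volume trends
#' comparable across methods of different absolute scale.
#'
#' @param volumes numeric vector of positive volumes, or a data.frame with
#'   columns `volume`, `roi` (optional) and `method` (optional).
#' @return normalized vector, or the data.frame with a `vnorm` column added.
#' @export
normalized_volumes <- function(volumes) {
  if (is.data.frame(volumes)) {
    if (any(volumes$volume <= 0)) stop("volumes must be strictly positive")
    grp <- interaction(
      if ("method" %in% names(volumes)) volumes$method else 0,
      if ("roi" %in% names(volumes)) volumes$roi else 0, drop = TRUE)
    volumes$vnorm <- volumes$volume / stats::ave(volumes$volume, grp)
    return(volumes)
  }
  if (any(volumes <= 0)) stop("volumes must be strictly positive")
  volumes / mean(volumes)
}

#' Binned reference volume curve from per-scan measurements
#'
#' Scans are grouped into fixed-width age bins; per-bin mean volumes are
#' normalized by the mean over bins (per ROI), and a per-bin 95% interval is
#' reported for plotting. Empty bins are reported as missing, never imputed.
#'
#' @param df data.frame with columns `age`, `volume`, and optionally `roi`.
#' @param bin_width bin width in years (default 2).
#' @param age_range range covered by the bins; defaults to the data range.
#' @return data.frame with columns `roi`, `bin_centre`, `n`, `volume`
#'   (bin mean), `vnorm`, `sd`, `ci_lo`, `ci_hi` (normalized scale).
#' @export
binned_reference_volumes <- function(df, bin_width = 2, age_range = NULL) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (is.null(df$roi)) df$roi <- "roi"
  if (is.null(age_range)) age_range <- range(df$age)
  edges <- seq(age_range[1], age_range[2] + bin_width * 0.999, by = bin_width)
  if (max(edges) < age_range[2]) edges <- c(edges, max(edges) + bin_width)
  centres <- utils::head(edges, -1) + bin_width / 2
  out <- NULL
  for (r in unique(df$roi)) {
    d <- df[df$roi == r, ]
    idx <- findInterval(d$age, edges, rightmost.closed = TRUE)
    means <- sds <- ns <- rep(NA_real_, length(centres))
    for (b in seq_along(centres)) {
      v <- d$volume[idx == b]
      ns[b] <- length(v)
      if (length(v)) {
        means[b] <- mean(v)
        sds[b] <- if (length(v) > 1) stats::sd(v) else 0
      }
    }
    mbar <- mean(means, na.rm = TRUE)
    se <- ifelse(ns > 0, sds / sqrt(pmax(ns, 1)), NA_real_)
    out <- rbind(out, data.frame(
      roi = r, bin_centre = centres, n = ns, volume = means,
      vnorm = means / mbar, sd = sds / mbar,
      ci_lo = (means - 1.96 * se) / mbar, ci_hi = (means + 1.96 * se) / mbar))
  }
  out
}

#' Agreement between a template volume curve and a reference curve
#'
#' Compares the normalized-volume trend measured on conditional templates
#' against the binned reference trend from individual scans: direction
#' (sign of the fitted linear slope), Spearman rank correlation between the
#' curves on the common age support, and the largest absolute
#' normalized-volume gap.
#'
#' @param template_curve data.frame with columns `age` (or `bin_centre`) and
#'   `vnorm`.
#' @param reference_curve same layout (missing bins dropped).
#' @return `list(sign_agreement, spearman, max_gap, slope_template,
#'   slope_reference)`.
#' @export
trend_recovery <- function(template_curve, reference_curve) {
  getcols <- function(d) {
    age <- if (!is.null(d$age)) d$age else d$bin_centre
    keep <- is.finite(age) & is.finite(d$vnorm)
    list(age = age[keep], v = d$vnorm[keep])
  }
  tc <- getcols(template_curve)
  rc <- getcols(reference_curve)
  if (length(tc$age) < 3 || length(rc$age) < 3)
    stop("need at least 3 support points per curve")
  # interpolate the reference onto the template support
  ref_at <- stats::approx(rc$age, rc$v, xout = tc$age, rule = 2)$y
  slope_t <- stats::coef(stats::lm(tc$v ~ tc$age))[2]
  slope_r <- stats::coef(stats::lm(rc$v ~ rc$age))[2]
  list(sign_agreement = unname(sign(slope_t) == sign(slope_r)),
       spearman = stats::cor(tc$v, ref_at, method = "spearman"),
       max_gap = max(abs(tc$v - ref_at)),
       slope_template = unname(slope_t),
       slope_reference = unname(slope_r))
}

#' Measure structure volumes on conditional templates
#'
#' The purely geometric analogue of segmenting each template: the group
#' template's ground-truth structure masks are warped through each
#' conditional deformation and summed. With `method = "linear"` (default)
#' each structure's indicator is warped with linear interpolation and the
#' warped mass is summed, giving a continuous volume that resolves sub-voxel
#' boundary shifts; `method = "nearest"` warps the integer label map with
#' nearest-neighbour interpolation and counts voxels, which quantizes volume
#' changes to whole voxels (adequate only when boundary displacements exceed
#' half a voxel).
#'
#' @param templates output of [build_templates()].
#' @param template_labels label `image_grid` of the group template.
#' @param rois named vector mapping ROI names to label values; defaults to the
#'   phantom labels.
#' @param method `"linear"` (soft indicator warp) or `"nearest"` (label
#'   counting).
#' @param adjusted use the mean-adjusted deformations instead.
#' @return data.frame with columns `age`, `roi`, `volume`.
#' @export
template_volumes <- function(templates, template_labels,
                             rois = c(gm = 1, wm = 2, vent = 3, hipp = 4),
                             method = c("linear", "nearest"),
                             adjusted = FALSE) {
  method <- match.arg(method)
  out <- NULL
  for (tp in templates) {
    phi <- if (adjusted) tp$phi_adj else tp$phi
    if (method == "nearest") {
      wl <- warp(template_labels, phi, mode = "nearest")
      vols <- vapply(rois, function(l) sum(round(wl$data) == l), numeric(1))
    } else {
      vols <- vapply(rois, function(l) {
        m <- image_grid((round(template_labels$data) == l) * 1.0,
                        spacing = template_labels$spacing)
        sum(warp(m, phi)$data)
      }, numeric(1))
    }
    out <- rbind(out, data.frame(age = tp$alpha, roi = names(rois),
                                 volume = unname(vols)))
  }
  out
}

#' Small-deformation SVF registration between two images
#'
#' An internal pairwise registration used by the evaluation battery (e.g. to
#' compare adjacent conditional templates after alignment): gradient descent
#' (Adam) on a full-resolution stationary velocity field under mean squared
#' intensity error plus a bending-energy penalty. This is the package's own
#' small-deformation aligner, not an external registration toolkit, and
#' reported comparisons label it as such.
#'
#' @param fixed,moving `image_grid`s on the same 2-D grid.
#' @param iters optimizer iterations.
#' @param lr Adam learning rate (voxel units).
#' @param lambda_bend bending-energy weight.
#' @param steps scaling-and-squaring steps.
#' @return `list(warped, phi, v, trace)`: the registered moving image, the
#'   deformation, the velocity field and the loss trace.
#' @export
register_pair <- function(fixed, moving, iters = 150, lr = 0.1,
                          lambda_bend = 0.01, steps = 7L) {
  check_same_grid(fixed, moving, "images")
  if (length(dim(fixed$data)) != 2L) stop("register_pair operates on 2-D images")
  r <- ca_register_cpp(as_matrix2(fixed), as_matrix2(moving),
                       as.integer(iters), lr, lambda_bend, as.integer(steps))
  g <- dim(fixed$data)
  list(warped = image_grid(array(r$warped, g), spacing = fixed$spacing),
       phi = vector_field(array(r$u, c(g, 2L)), role = "deformation"),
       v = vector_field(array(r$v, c(g, 2L)), role = "velocity"),
       trace = r$trace)
}
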