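#' Specification of the synthetic age-dependent brain phantom
#'
#' The phantom emulates the statistical structure the template model
#' consumes: skull-stripped, affinely aligned T1-like 2-D slices whose
#' structures change smoothly with age. Anatomy is an elliptical brain with a
#' cortical grey-matter ribbon, white-matter interior, paired dark ventricle
#' lobes and paired bright hippocampus discs. Structure areas follow
#' configurable age trends (ventricles grow, hippocampus and cortical grey
#' matter shrink, white matter shrinks mildly via slight whole-brain
#' atrophy); per-subject jitter perturbs sizes and positions. Intensities are
#' T1-like: white matter bright, grey matter intermediate, CSF dark, in
#' \[0, 1\]. No MRI physics (bias field, partial volume) is simulated.
#'
#' @param grid image dimensions (2-D).
#' @param age_range ages covered by the generator (years).
#' @param vent_change,hipp_change,gm_change,brain_change total fractional area
#'   change of each structure across `age_range` (e.g. `0.5` means +50% from
#'   the youngest to the oldest age). `brain_change` shrinks the whole brain
#'   outline, which is what gives white matter (the residual interior) its
#'   mild decline.
#' @param jitter_size lognormal sd of per-subject structure-size factors.
#' @param jitter_pos uniform half-range (voxels) of per-subject structure
#'   centre offsets.
#' @param intensities named intensities for `gm`, `wm`, `vent`, `hipp`.
#' @param noise_snr if non-`NULL`, additive-noise corruption targeting this
#'   fraction of the clean image's signal-to-noise ratio (see
#'   [corrupt_noise()]).
#' @param contrast_a if non-`NULL`, random gamma-contrast corruption with
#'   exponent `exp(beta)`, `beta ~ U(-a, a)` (see [corrupt_contrast()]).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(64L, 64L),
                         age_range = c(50, 90),
                         vent_change = 0.5,
                         hipp_change = -0.15,
                         gm_change = -0.10,
                         brain_change = -0.03,
                         jitter_size = 0.03,
                         jitter_pos = 1.0,
                         intensities = c(gm = 0.5, wm = 0.85,
                                         vent = 0.12, hipp = 0.65),
                         noise_snr = NULL,
                         contrast_a = NULL) {
  if (any(intensities < 0 | intensities > 1))
    stop("intensities must lie in [0, 1]")
  structure(list(grid = as.integer(grid), age_range = as.numeric(age_range),
                 vent_change = vent_change, hipp_change = hipp_change,
                 gm_change = gm_change, brain_change = brain_change,
                 jitter_size = jitter_size, jitter_pos = jitter_pos,
                 intensities = intensities, noise_snr = noise_snr,
                 contrast_a = contrast_a),
            class = "phantom_spec")
}

# Area factor linear in age, parameterised by the total change across the age
# range: f(young) = 1 - c, f(old) = 1 + c with (1+c)/(1-c) = 1 + change.
age_factor <- function(alpha, age_range, change) {
  r <- 1 + change
  c <- (r - 1) / (r + 1)
  mid <- mean(age_range)
  half <- diff(age_range) / 2
  1 + c * (alpha - mid) / half
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

ellipse_mask <- function(i, j, centre, semi) {
  ((i - centre[1]) / semi[1])^2 + ((j - centre[2]) / semi[2])^2 <= 1
}

# Base geometry at the grid scale (fractions of a 64-voxel reference frame).
phantom_geometry <- function(grid) {
  s <- min(grid) / 64
  list(centre = (grid - 1) / 2,
       brain = c(25, 21) * s,         # outer semi-axes
       gm_thick = 3.5 * s,            # ribbon thickness
       vent_semi = c(7, 3) * s,       # each lobe
       vent_off = 4.5 * s,            # lateral offset of lobe centres
       hipp_semi = c(3.6, 2.6) * s,   # elongated hippocampal body
       hipp_off = c(10.3, 8.6) * s)   # (inferior, lateral) offsets
}

#' Generate one synthetic phantom
#'
#' Deterministic given `(spec, alpha, seed)`. Structure areas follow the
#' spec's age trends with seeded per-subject jitter; the label map is exactly
#' aligned with the intensities, and true volumes are voxel counts per label.
#' If jittered structures would overlap or escape the white-matter interior,
#' the jitter is redrawn (up to 20 retries).
#'
#' @param spec a [phantom_spec()].
#' @param alpha age in years, within the spec's range.
#' @param seed integer seed for subject jitter and corruption; `NULL` for the
#'   jitter-free canonical anatomy at that age.
#' @return `list(image, labels, volumes)`: the intensity `image_grid`, a label
#'   `image_grid` (0 background, 1 cortical GM, 2 WM, 3 ventricles,
#'   4 hippocampus), and named true volumes (voxel counts).
#' @export
generate_phantom <- function(spec, alpha, seed = NULL) {
  if (alpha < spec$age_range[1] || alpha > spec$age_range[2])
    stop("alpha outside the spec's age range")
  with_seed(seed, {
    geo <- phantom_geometry(spec$grid)
    n1 <- spec$grid[1]; n2 <- spec$grid[2]
    i <- matrix(seq_len(n1) - 1, n1, n2)
    j <- matrix(seq_len(n2) - 1, n1, n2, byrow = TRUE)
    f_v <- age_factor(alpha, spec$age_range, spec$vent_change)
    f_h <- age_factor(alpha, spec$age_range, spec$hipp_change)
    f_g <- age_factor(alpha, spec$age_range, spec$gm_change)
    f_b <- age_factor(alpha, spec$age_range, spec$brain_change)

    jit <- function() if (is.null(seed)) 1 else exp(stats::rnorm(1, sd = spec$jitter_size))
    pjit <- function(k) if (is.null(seed)) numeric(k) else
      stats::runif(k, -spec$jitter_pos, spec$jitter_pos)

    for (attempt in 1:20) {
      centre <- geo$centre + pjit(2) * 0.5
      brain_semi <- geo$brain * sqrt(f_b * jit())
      gm_t <- geo$gm_thick * f_g * jit()
      vent_semi <- geo$vent_semi * sqrt(f_v * jit())
      vent_c1 <- centre + c(0, -geo$vent_off) + pjit(2) * 0.5
      vent_c2 <- centre + c(0, geo$vent_off) + pjit(2) * 0.5
      hipp_semi <- geo$hipp_semi * sqrt(f_h * jit())
      hipp_c1 <- centre + c(geo$hipp_off[1], -geo$hipp_off[2]) + pjit(2)
      hipp_c2 <- centre + c(geo$hipp_off[1], geo$hipp_off[2]) + pjit(2)

      outer <- ellipse_mask(i, j, centre, brain_semi)
      inner <- ellipse_mask(i, j, centre, pmax(brain_semi - gm_t, 1))
      vent <- ellipse_mask(i, j, vent_c1, vent_semi) |
              ellipse_mask(i, j, vent_c2, vent_semi)
      hipp <- ellipse_mask(i, j, hipp_c1, hipp_semi) |
              ellipse_mask(i, j, hipp_c2, hipp_semi)
      ok <- all(vent[!inner] == FALSE) && all(hipp[!inner] == FALSE) &&
            !any(vent & hipp) && any(vent) && any(hipp)
      if (ok) break
      if (attempt == 20) stop("structures overlap after jitter; spec too tight")
    }

    labels <- matrix(0L, n1, n2)
    labels[outer & !inner] <- 1L
    labels[inner] <- 2L
    labels[vent] <- 3L
    labels[hipp] <- 4L

    ints <- spec$intensities
    img <- matrix(0, n1, n2)
    img[labels == 1L] <- ints[["gm"]]
    img[labels == 2L] <- ints[["wm"]]
    img[labels == 3L] <- ints[["vent"]]
    img[labels == 4L] <- ints[["hipp"]]

    volumes <- c(gm = sum(labels == 1L), wm = sum(labels == 2L),
                 vent = sum(labels == 3L), hipp = sum(labels == 4L))

    out <- image_grid(img)
    if (!is.null(spec$contrast_a))
      out <- corrupt_contrast(out, spec$contrast_a,
                              seed = if (is.null(seed)) NULL else seed + 1L)
    if (!is.null(spec$noise_snr))
      out <- corrupt_noise(out, spec$noise_snr,
                           seed = if (is.null(seed)) NULL else seed + 2L)
    list(image = out, labels = image_grid(labels + 0), volumes = volumes)
  })
}

#' Additive Gaussian noise targeting a fraction of the input SNR
#'
#' SNR convention (declared and used consistently throughout the package):
#' mean foreground intensity divided by the foreground intensity standard
#' deviation, with foreground all voxels above 5% of the maximum. Noise of
#' standard deviation \eqn{\sigma = s\sqrt{1/f^2 - 1}} (where `s` is the
#' input's foreground sd and `f` the target fraction) makes the corrupted
#' image's measured SNR equal `f` times the input's, since independent noise
#' adds in quadrature.
#'
#' @param img an `image_grid`.
#' @param snr_fraction target SNR fraction in (0, 1].
#' @param seed integer seed for the noise draw.
#' @return the corrupted `image_grid` (not clipped).
#' @export
corrupt_noise <- function(img, snr_fraction, seed = NULL) {
  if (snr_fraction <= 0 || snr_fraction > 1)
    stop("snr_fraction must lie in (0, 1]")
  fg <- img$data > 0.05 * max(img$data)
  if (!any(fg) || mean(img$data[fg]) == 0)
    stop("zero-signal image: SNR undefined")
  s <- stats::sd(img$data[fg])
  if (snr_fraction == 1) return(img)
  sigma <- s * sqrt(1 / snr_fraction^2 - 1)
  with_seed(seed, {
    noisy <- img$data + array(stats::rnorm(length(img$data), sd = sigma),
                              dim(img$data))
    image_grid(noisy, spacing = img$spacing, affine = img$affine)
  })
}

#' Measured SNR of an image (package convention)
#'
#' SNR is mean foreground intensity divided by foreground standard deviation.
#' When comparing a corrupted image against its clean original, pass the
#' clean image's foreground mask so both measurements use the same voxels.
#'
#' @param img an `image_grid`.
#' @param mask optional logical foreground mask; derived from `img` by
#'   thresholding if omitted.
#' @param fg_threshold foreground threshold as a fraction of the maximum.
#' @return mean(foreground) / sd(foreground).
#' @export
measure_snr <- function(img, mask = NULL, fg_threshold = 0.05) {
  if (is.null(mask)) mask <- img$data > fg_threshold * max(img$data)
  mean(img$data[mask]) / stats::sd(img$data[mask])
}

#' Random gamma-contrast corruption
#'
#' Draws one exponent per image, \eqn{\gamma = e^\beta} with
#' \eqn{\beta \sim U(-a, a)}, and raises every voxel intensity to that power.
#' Requires intensities in \[0, 1\].
#'
#' @param img an `image_grid` with intensities in \[0, 1\].
#' @param a half-range of the uniform draw of `beta` (default 0.3).
#' @param seed integer seed.
#' @param beta optional fixed exponent parameter overriding the random draw
#'   (for reproducible pipelines and testing).
#' @return the corrupted `image_grid`; the realized exponent is attached as
#'   attribute `"gamma"`.
#' @export
corrupt_contrast <- function(img, a = 0.3, seed = NULL, beta = NULL) {
  if (a < 0) stop("a must be non-negative")
  if (min(img$data) < 0) stop("gamma correction undefined for negative intensities")
  if (max(img$data) > 1 + 1e-8) stop("intensities must lie in [0, 1]")
  with_seed(seed, {
    if (is.null(beta)) beta <- stats::runif(1, -a, a)
    g <- exp(beta)
    out <- image_grid(img$data^g, spacing = img$spacing, affine = img$affine)
    attr(out, "gamma") <- g
    out
  })
}

#' Group template from the phantom generator
#'
#' The noise-free phantom at the mid-range age with zero jitter: a clean,
#' detailed reference anatomy playing the role of a pre-built group template.
#' Ground-truth labels are carried along so that template volumes can be
#' measured geometrically (labels warped through predicted deformations).
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects kept for interface symmetry; the zero-jitter template
#'   does not depend on it.
#' @param seed unused in zero-jitter mode.
#' @return `list(image, labels, volumes)` of class `group_template`.
#' @export
build_group_template <- function(spec, n_subjects = 1L, seed = NULL) {
  clean <- spec
  clean$noise_snr <- NULL
  clean$contrast_a <- NULL
  out <- generate_phantom(clean, mean(spec$age_range), seed = NULL)
  class(out) <- "group_template"
  out
}

#' @export
print.group_template <- function(x, ...) {
  cat("<group_template>\n")
  print(x$image)
  invisible(x)
}

#' Generate an in-memory phantom dataset
#'
#' Ages are drawn uniformly over the spec's range (seeded); each subject gets
#' an independent jitter/corruption seed derived from the master seed.
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects.
#' @param seed master seed.
#' @param ages optional explicit ages (length `n`); drawn uniformly if `NULL`.
#' @return `list(template, template_labels, images, labels, alphas, volumes)`
#'   where `volumes` is a data.frame (one row per subject) of true voxel
#'   counts, suitable for [run_training()].
#' @export
generate_phantom_dataset <- function(spec, n, seed = 1L, ages = NULL) {
  gt <- build_group_template(spec)
  with_seed(seed, {
    if (is.null(ages))
      ages <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    seeds <- sample.int(2^30, n)
    phs <- lapply(seq_len(n), function(k) generate_phantom(spec, ages[k], seeds[k]))
    list(template = gt$image, template_labels = gt$labels,
         images = lapply(phs, function(p) p$image),
         labels = lapply(phs, function(p) p$labels),
         alphas = ages,
         volumes = cbind(data.frame(age = ages),
                         do.call(rbind, lapply(phs, function(p)
                           as.data.frame(as.list(p$volumes))))))
  })
}

#' Write a phantom dataset to disk (NIfTI images + manifest CSV)
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects.
#' @param dir output directory (created if needed).
#' @param seed master seed.
#' @param ages optional explicit ages.
#' @return the manifest data.frame (also written to `manifest.csv`): columns
#'   `path`, `label_path`, `age`, `sex` and true per-structure volumes.
#' @export
write_phantom_dataset <- function(spec, n, dir, seed = 1L, ages = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ds <- generate_phantom_dataset(spec, n, seed = seed, ages = ages)
  write_image(ds$template, file.path(dir, "template.nii.gz"))
  write_image(ds$template_labels, file.path(dir, "template_labels.nii.gz"))
  paths <- character(n); lpaths <- character(n)
  for (k in seq_len(n)) {
    paths[k] <- file.path(dir, sprintf("phantom_%04d.nii.gz", k))
    lpaths[k] <- file.path(dir, sprintf("phantom_%04d_labels.nii.gz", k))
    write_image(ds$images[[k]], paths[k])
    write_image(ds$labels[[k]], lpaths[k])
  }
  manifest <- cbind(data.frame(path = paths, label_path = lpaths,
                               age = ds$alphas, sex = NA_character_),
                    ds$volumes[, -1, drop = FALSE])
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
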