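#' Read a NIfTI image into an `image_grid`
#'
#' Data, voxel spacing and the voxel-to-world affine round-trip losslessly;
#' intensities are never rescaled silently (use `rescale = TRUE` to map to
#' \[0, 1\], recorded in the returned object's `"rescale"` attribute).
#'
#' @param path a `.nii` or `.nii.gz` file.
#' @param rescale map intensities linearly to \[0, 1\]?
#' @return an `image_grid`.
#' @export
read_image <- function(path, rescale = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  data <- structure(as.vector(as.array(nii)), dim = dim(nii))
  nd <- length(dim(data))
  if (nd > 3L) stop("4-D input rejected (single-channel volumes only): ", path)
  spacing <- RNifti::pixdim(nii)[seq_len(nd)]
  affine <- tryCatch(structure(RNifti::xform(nii), class = NULL),
                     error = function(e) diag(4))
  img <- image_grid(data, spacing = spacing, affine = affine)
  if (rescale) {
    rng <- range(img$data)
    if (diff(rng) > 0)
      img$data <- (img$data - rng[1]) / diff(rng)
    attr(img, "rescale") <- rng
  }
  img
}

#' Write an `image_grid` to NIfTI
#'
#' @param img an `image_grid`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_image <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- img$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read / write a vector field as multi-component NIfTI with a JSON sidecar
#'
#' The component axis is stored as the trailing NIfTI dimension; the sidecar
#' (`<path>.json`) records the field role and the voxel-unit displacement
#' convention so that round-trips restore an identical `vector_field`.
#'
#' @param field a `vector_field`.
#' @param path output path.
#' @export
write_field <- function(field, path) {
  nii <- RNifti::asNifti(field$data)
  RNifti::writeNifti(nii, path)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(list(role = field$role, units = "voxel",
                            convention = "displacement from identity"),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  nii <- RNifti::readNifti(path)
  data <- structure(as.vector(as.array(nii)), dim = dim(nii))
  sidecar <- paste0(path, ".json")
  role <- "deformation"
  if (file.exists(sidecar)) role <- jsonlite::read_json(sidecar)$role
  vector_field(data, role = role)
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with columns `path`, `age`, and optionally `sex`,
#' `label_path`, `participant` and true-volume columns. Paths are checked to
#' resolve, ages to be finite, and duplicate paths rejected.
#'
#' @param path CSV path; relative image paths resolve against its directory.
#' @return the validated manifest data.frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "age") %in% names(m)))
    stop("manifest needs at least 'path' and 'age' columns")
  base <- dirname(path)
  abs <- ifelse(file.exists(m$path), m$path, file.path(base, m$path))
  if (any(!file.exists(abs)))
    stop("unresolvable image path(s): ",
         paste(utils::head(m$path[!file.exists(abs)], 3), collapse = ", "))
  m$path <- abs
  if ("label_path" %in% names(m)) {
    labs <- ifelse(file.exists(m$label_path), m$label_path,
                   file.path(base, m$label_path))
    m$label_path <- labs
  }
  if (any(!is.finite(m$age))) stop("all ages must be finite")
  if (anyDuplicated(m$path)) stop("duplicate image paths in manifest")
  m
}

#' Load a manifest's images into an in-memory dataset
#'
#' @param manifest data.frame from [read_manifest()].
#' @param template_path path to the group template image.
#' @return a dataset list for [run_training()].
#' @export
load_dataset <- function(manifest, template_path) {
  list(template = read_image(template_path),
       images = lapply(manifest$path, read_image),
       alphas = manifest$age)
}

#' Participant-disjoint train/validation/test split
#'
#' Rows sharing a participant identifier never span two partitions. With one
#' scan per participant the partition sizes equal `round(fractions * n)`
#' exactly (remainder assigned to the training set).
#'
#' @param manifest data.frame with at least one row; a `participant` column
#'   groups scans of the same subject (row identity otherwise).
#' @param fractions train/val/test fractions summing to 1.
#' @param seed split seed.
#' @return `list(train, val, test)` of manifest subsets.
#' @export
split_manifest <- function(manifest, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stop("fractions must be non-negative and sum to 1")
  ids <- if ("participant" %in% names(manifest)) manifest$participant
         else seq_len(nrow(manifest))
  uid <- unique(ids)
  with_seed(seed, {
    ord <- sample(uid)
    counts <- table(factor(ids, levels = uid))[as.character(ord)]
    n <- nrow(manifest)
    target <- round(fractions * n)
    target[1] <- n - sum(target[-1])
    grp <- integer(length(ord))
    placed <- c(0, 0, 0)
    for (i in seq_along(ord)) {
      k <- which(placed + counts[i] <= target)
      k <- if (length(k)) k[1] else which.min(placed / pmax(target, 1))
      grp[i] <- k
      placed[k] <- placed[k] + counts[i]
    }
    pick <- function(k) manifest[ids %in% ord[grp == k], , drop = FALSE]
    list(train = pick(1), val = pick(2), test = pick(3))
  })
}
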