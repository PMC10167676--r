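#' Jacobian determinant volumes
#'
#' A `jacobian_volume` wraps a 3-D voxel grid of regional volume-change
#' values together with voxel size and processing-stage metadata. Values are
#' dimensionless expansion/contraction factors before the log transform and
#' unit-interval intensities after cohort-wide scaling.
#'
#' @param voxels A numeric 3-D array.
#' @param voxel_size_mm Numeric length-3 voxel edge lengths in millimetres.
#' @param subject_id Optional subject identifier.
#' @param stage Processing stage, one of `"raw"`, `"smoothed"`, `"logged"`,
#'   `"scaled"`.
#' @return A `jacobian_volume` object.
#' @export
jacobian_volume <- function(voxels, voxel_size_mm = c(1, 1, 1),
                            subject_id = NA_character_, stage = "raw") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  if (any(dim(voxels) <= 0L)) stop("all dims must be strictly positive", call. = FALSE)
  stage <- match.arg(stage, c("raw", "smoothed", "logged", "scaled"))
  voxel_size_mm <- rep_len(as.numeric(voxel_size_mm), 3L)
  structure(
    list(
      voxels = voxels,
      voxel_size_mm = voxel_size_mm,
      subject_id = as.character(subject_id),
      stage = stage
    ),
    class = "jacobian_volume"
  )
}

#' @export
print.jacobian_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<jacobian_volume> %s  %d x %d x %d @ %.3g mm  stage: %s\n",
    x$subject_id, d[1], d[2], d[3], x$voxel_size_mm[1], x$stage
  ))
  invisible(x)
}

#' @export
dim.jacobian_volume <- function(x) dim(x$voxels)

#' Binary brain mask
#'
#' @param voxels A 3-D array coercible to logical; non-zero marks in-mask.
#' @return A `brain_mask` object.
#' @export
brain_mask <- function(voxels) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3-D array", call. = FALSE)
  }
  v <- array(voxels != 0, dim = dim(voxels))
  if (!any(v)) stop("mask must contain at least one in-mask voxel", call. = FALSE)
  structure(list(voxels = v), class = "brain_mask")
}

#' @export
dim.brain_mask <- function(x) dim(x$voxels)

#' Read a NIfTI volume
#'
#' Reads a 3-D NIfTI-1 image into a [jacobian_volume()] without modifying
#' voxel values. Grid dimensions and voxel size come from the header.
#'
#' @param path Path to a NIfTI file (`.nii` or `.nii.gz`).
#' @param subject_id Optional subject identifier to attach.
#' @param stage Processing stage to record (the file itself carries none).
#' @return A `jacobian_volume`.
#' @export
read_volume <- function(path, subject_id = NA_character_, stage = "raw") {
  if (!file.exists(path)) {
    stop(sprintf("NIfTI file not found: '%s'", path), call. = FALSE)
  }
  img <- tryCatch(
    RNifti::readNifti(path),
    error = function(e) stop(sprintf("unreadable NIfTI header in '%s': %s", path, conditionMessage(e)), call. = FALSE)
  )
  d <- dim(img)
  if (length(d) != 3L) {
    stop(sprintf("expected a 3-D image, got %d dimension(s)", length(d)), call. = FALSE)
  }
  vox <- RNifti::pixdim(img)[seq_len(3L)]
  jacobian_volume(array(as.numeric(img), dim = d),
                  voxel_size_mm = vox, subject_id = subject_id, stage = stage)
}

#' Write a volume or mask to NIfTI
#'
#' @param v A `jacobian_volume` or `brain_mask`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  if (inherits(v, "brain_mask")) {
    img <- RNifti::asNifti(array(as.numeric(v$voxels), dim = dim(v$voxels)))
  } else if (inherits(v, "jacobian_volume")) {
    img <- RNifti::asNifti(v$voxels)
    RNifti::pixdim(img) <- v$voxel_size_mm
  } else {
    stop("`v` must be a jacobian_volume or brain_mask", call. = FALSE)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1-D Gaussian kernel matrix: row i holds the kernel centred at i, truncated
# at the grid edges and renormalized to unit mass so that constant fields are
# exactly preserved (away from the edges the rows already sum to one and the
# renormalization is a no-op).
gaussian_kernel_matrix <- function(n, sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  offs <- (-half):half
  k <- exp(-offs^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    m[i, j[ok]] <- m[i, j[ok]] + k[ok]
    m[i, ] <- m[i, ] / sum(m[i, ])
  }
  m
}

# Separable 3-D convolution of a plain array by axis-wise kernel matrices.
smooth_array <- function(a, sigma_vox) {
  d <- dim(a)
  kx <- gaussian_kernel_matrix(d[1], sigma_vox[1])
  ky <- gaussian_kernel_matrix(d[2], sigma_vox[2])
  kz <- gaussian_kernel_matrix(d[3], sigma_vox[3])
  dim(a) <- c(d[1], d[2] * d[3])
  a <- kx %*% a
  dim(a) <- d
  a <- aperm(a, c(2L, 1L, 3L))
  dim(a) <- c(d[2], d[1] * d[3])
  a <- ky %*% a
  dim(a) <- c(d[2], d[1], d[3])
  a <- aperm(a, c(3L, 2L, 1L))
  dim(a) <- c(d[3], d[1] * d[2])
  a <- kz %*% a
  dim(a) <- c(d[3], d[1], d[2])
  aperm(a, c(2L, 3L, 1L))
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian convolution with per-axis standard deviation
#' `fwhm_mm / (2 sqrt(2 ln 2)) / voxel_size_mm`. The kernel is truncated at
#' the grid boundary and renormalized there, so constant fields pass through
#' unchanged.
#'
#' @param v A `jacobian_volume` with known voxel size.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm.
#' @return The smoothed volume, stage `"smoothed"`.
#' @export
gaussian_smooth <- function(v, fwhm_mm = 8) {
  stopifnot(inherits(v, "jacobian_volume"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0) {
    stop("`fwhm_mm` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(v$voxel_size_mm)) || any(v$voxel_size_mm <= 0)) {
    stop("voxel size unknown or non-positive; cannot convert FWHM to voxels", call. = FALSE)
  }
  sigma_vox <- fwhm_mm / fwhm_to_sigma_factor() / v$voxel_size_mm
  out <- v
  out$voxels <- smooth_array(v$voxels, sigma_vox)
  out$stage <- "smoothed"
  out
}

#' @rdname gaussian_smooth
#' @export
fwhm_to_sigma_factor <- function() 2 * sqrt(2 * log(2))

#' Voxelwise natural log transform
#'
#' Applied within the mask only (out-of-mask voxels are set to zero). A
#' non-positive in-mask value signals an invalid Jacobian and is an error.
#'
#' @param v A `jacobian_volume`.
#' @param mask Optional `brain_mask`; default treats every voxel as in-mask.
#' @return The transformed volume, stage `"logged"`.
#' @export
log_transform <- function(v, mask = NULL) {
  stopifnot(inherits(v, "jacobian_volume"))
  m <- if (is.null(mask)) array(TRUE, dim(v$voxels)) else {
    stopifnot(inherits(mask, "brain_mask"))
    if (!identical(dim(mask$voxels), dim(v$voxels))) stop("mask dims mismatch", call. = FALSE)
    mask$voxels
  }
  if (any(v$voxels[m] <= 0)) {
    stop("non-positive in-mask Jacobian value; log transform undefined", call. = FALSE)
  }
  out <- v
  vox <- array(0, dim(v$voxels))
  vox[m] <- log(v$voxels[m])
  out$voxels <- vox
  out$stage <- "logged"
  out
}

#' Cohort-wide unit-interval scaling
#'
#' Maps the single global minimum and maximum over all in-mask voxels of all
#' volumes linearly to \[0, 1\], applying the same affine to every volume so
#' intensities stay comparable across the dataset.
#'
#' @param volumes A list of `jacobian_volume`s at stage `"logged"` (or later).
#' @param mask Optional shared `brain_mask` restricting the min/max search.
#' @return A list of scaled volumes, stage `"scaled"`.
#' @export
scale_dataset_unit_interval <- function(volumes, mask = NULL) {
  if (length(volumes) < 1L) stop("need at least one volume", call. = FALSE)
  sel <- if (is.null(mask)) NULL else mask$voxels
  rngs <- vapply(volumes, function(v) {
    x <- if (is.null(sel)) v$voxels else v$voxels[sel]
    range(x)
  }, numeric(2))
  lo <- min(rngs[1, ]); hi <- max(rngs[2, ])
  if (hi <= lo) stop("degenerate scaling: global max equals global min", call. = FALSE)
  lapply(volumes, function(v) {
    out <- v
    out$voxels <- (v$voxels - lo) / (hi - lo)
    if (!is.null(sel)) out$voxels[!sel] <- 0
    out$stage <- "scaled"
    out
  })
}

#' Apply a brain mask
#'
#' Sets out-of-mask voxels to zero; in-mask voxels are untouched.
#'
#' @param v A `jacobian_volume`.
#' @param m A `brain_mask` with matching dims.
#' @return The masked volume (stage unchanged).
#' @export
apply_mask <- function(v, m) {
  stopifnot(inherits(v, "jacobian_volume"), inherits(m, "brain_mask"))
  if (!identical(dim(v$voxels), dim(m$voxels))) {
    stop("volume and mask dims mismatch", call. = FALSE)
  }
  out <- v
  out$voxels[!m$voxels] <- 0
  out
}

#' Full Jacobian post-processing chain
#'
#' Convenience wrapper applying, in order: Gaussian smoothing, log
#' transform, cohort-wide unit scaling, and masking.
#'
#' @param volumes List of raw `jacobian_volume`s.
#' @param mask A shared `brain_mask`.
#' @param fwhm_mm Smoothing kernel FWHM in mm.
#' @return List of processed volumes at stage `"scaled"`, masked.
#' @export
preprocess_volumes <- function(volumes, mask, fwhm_mm = 8) {
  sm <- lapply(volumes, gaussian_smooth, fwhm_mm = fwhm_mm)
  lg <- lapply(sm, log_transform)
  sc <- scale_dataset_unit_interval(lg)
  lapply(sc, apply_mask, m = mask)
}
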