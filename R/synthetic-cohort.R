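#' Planted effect region
#'
#' A spherical region in which one group's (log-scale) intensity is shifted
#' by a known amount, providing ground truth for classification and
#' saliency recovery.
#'
#' @param center Integer voxel triple (1-based).
#' @param radius_voxels Sphere radius in voxels (>= 1).
#' @param group_shift Additive mean shift on the pre-scaling (log) scale.
#' @param target_group `"case"` or `"control"`.
#' @return An `effect_region` object.
#' @export
effect_region <- function(center, radius_voxels, group_shift,
                          target_group = c("case", "control")) {
  target_group <- match.arg(target_group)
  if (radius_voxels < 1) stop("`radius_voxels` must be >= 1", call. = FALSE)
  structure(
    list(center = as.numeric(center), radius_voxels = as.numeric(radius_voxels),
         group_shift = as.numeric(group_shift), target_group = target_group),
    class = "effect_region"
  )
}

region_indicator <- function(region, dims) {
  cx <- region$center
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  d2 <- (g$x - cx[1])^2 + (g$y - cx[2])^2 + (g$z - cx[3])^2
  array(d2 <= region$radius_voxels^2, dim = dims)
}

check_region_fits <- function(region, dims) {
  lo <- region$center - region$radius_voxels
  hi <- region$center + region$radius_voxels
  if (any(lo < 1) || any(hi > dims)) {
    stop("effect region sphere does not fit within the grid", call. = FALSE)
  }
  invisible(TRUE)
}

#' Default site composition
#'
#' Five research sites with unequal sampling; site E is deliberately
#' over-imbalanced towards cases (22 cases vs 4 controls at the reference
#' cohort size of 96 + 96) to emulate consortium site imbalance.
#'
#' @return A tibble with `site`, `prop_cases`, `prop_controls`.
#' @export
default_sites <- function() {
  tibble::tibble(
    site = c("A", "B", "C", "D", "E"),
    prop_cases = c(30, 20, 14, 10, 22) / 96,
    prop_controls = c(34, 24, 18, 16, 4) / 96
  )
}

#' Default planted effect regions
#'
#' Two spherical regions scaled to the grid: one where cases show relative
#' expansion and one where controls do, mimicking group-specific regional
#' volume effects.
#'
#' @param dims Grid dims the regions are placed in.
#' @param group_shift Log-scale mean shift magnitude (default 0.75, five
#'   times the default subject noise SD: a strongly recoverable effect).
#' @return List of [effect_region()]s.
#' @export
default_regions <- function(dims = c(40L, 48L, 40L), group_shift = 0.75) {
  r <- max(3, round(min(dims) / 10))
  list(
    effect_region(round(dims * c(0.35, 0.40, 0.40)), r, group_shift, "case"),
    effect_region(round(dims * c(0.65, 0.62, 0.58)), r, group_shift, "control")
  )
}

# ellipsoidal brain-like mask centred in the grid
ellipsoid_mask <- function(dims, semi_frac = 0.44) {
  c0 <- (dims + 1) / 2
  ax <- semi_frac * dims
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  inside <- ((g$x - c0[1]) / ax[1])^2 + ((g$y - c0[2]) / ax[2])^2 +
    ((g$z - c0[3]) / ax[3])^2 <= 1
  brain_mask(array(inside, dim = dims))
}

largest_remainder <- function(props, n) {
  raw <- props * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

score_names <- function() c("WA", "WID", "PC", "RAN", "VIQ")

#' Generate a synthetic Jacobian cohort with planted ground truth
#'
#' Each subject's raw (log-scale) field is a shared smooth background plus
#' i.i.d. Gaussian subject noise plus the planted group shift inside each
#' effect region for its target group. Fields are then Gaussian smoothed,
#' unit-scaled cohort-wide and masked, so volumes satisfy all processed
#' Jacobian invariants. Behavioral standard scores are drawn as
#' `100 - score_effect * z(region mean intensity) + noise`, so a score
#' correlates (with known sign) with the intensity of its driving region
#' and case scores centre below control scores.
#'
#' @param n_cases,n_controls Group sizes (> 0).
#' @param dims Grid dims; default 40 x 48 x 40, a desk-scale grid
#'   preserving the 121:145:121 aspect ratio.
#' @param sites Data frame with `site`, `prop_cases`, `prop_controls`
#'   (per-group proportions summing to 1) — see [default_sites()].
#' @param regions List of [effect_region()]s; see [default_regions()].
#' @param subject_noise_sd SD of the subject-specific deviation field on
#'   the log scale, before the output smoothing (default 0.15, a typical
#'   regional log-Jacobian spread).
#' @param fwhm_mm Output smoothing kernel FWHM (default 8 mm).
#' @param deformation_fwhm_mm Intrinsic correlation length of the
#'   subject deviation field (default 12 mm). Jacobian maps derive from
#'   regularized diffeomorphic warps, so subject-to-subject differences are
#'   smooth at the warp-regularization scale before any output smoothing;
#'   the deviation field is i.i.d. Gaussian innovation smoothed to this
#'   scale and rescaled to `subject_noise_sd`.
#' @param empty_space_log Log-scale floor assigned to voxels outside the
#'   brain before smoothing (default -2): empty space carries a strongly
#'   compressive Jacobian, which is why after unit scaling the out-of-brain
#'   intensities sit near zero and the `a > 0` mask removes little signal.
#' @param voxel_size_mm Isotropic voxel edge (default 1 mm: the desk grid emulates the voxel-level smoothness of the full-size data on a smaller field of view).
#' @param background_sd SD of the shared smooth background field.
#' @param score_effect Standard-score points per SD of driving-region
#'   intensity (default 5).
#' @param score_noise_sd Residual score noise SD (default 10).
#' @param seed Integer seed; the cohort is bit-identical given the seed.
#' @return A `cohort`: `subjects` tibble (`subject_id`, `group`, `site`,
#'   `age`, `sex`, scores, `total_brain_volume`), `volumes` (list of
#'   processed `jacobian_volume`s), `mask`, `truth` (regions), `seed`.
#' @export
generate_cohort <- function(n_cases, n_controls, dims = c(40L, 48L, 40L),
                            sites = default_sites(),
                            regions = default_regions(dims),
                            subject_noise_sd = 0.15, fwhm_mm = 8,
                            deformation_fwhm_mm = 12,
                            voxel_size_mm = 1, background_sd = 0.5,
                            empty_space_log = -2,
                            score_effect = 5, score_noise_sd = 10,
                            seed = 1L) {
  if (n_cases < 1L || n_controls < 1L) stop("group sizes must be positive", call. = FALSE)
  if (nrow(sites) < 1L) stop("site table is empty", call. = FALSE)
  dims <- as.integer(dims)
  for (rg in regions) check_region_fits(rg, dims)
  set.seed(seed)

  mask <- ellipsoid_mask(dims)
  sigma_vox <- rep(fwhm_mm / fwhm_to_sigma_factor() / voxel_size_mm, 3L)
  sigma_dev <- rep(deformation_fwhm_mm / fwhm_to_sigma_factor() / voxel_size_mm, 3L)

  # shared background: broadly smoothed white noise rescaled to background_sd
  bg <- smooth_array(array(stats::rnorm(prod(dims)), dims), sigma_vox * 3)
  bg <- bg / stats::sd(bg[mask$voxels]) * background_sd

  case_n <- largest_remainder(sites$prop_cases, n_cases)
  ctrl_n <- largest_remainder(sites$prop_controls, n_controls)
  n <- n_cases + n_controls
  subjects <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = c(rep("case", n_cases), rep("control", n_controls)),
    site = c(rep(sites$site, case_n), rep(sites$site, ctrl_n)),
    age = round(stats::rnorm(n, 9.86, 1.56), 2),
    sex = sample(c("F", "M"), n, replace = TRUE),
    total_brain_volume = round(stats::rnorm(n, 1.2e6, 1e5))
  )

  region_masks <- lapply(regions, region_indicator, dims = dims)
  shift_field <- list(
    case = array(0, dims), control = array(0, dims)
  )
  for (i in seq_along(regions)) {
    g <- regions[[i]]$target_group
    shift_field[[g]][region_masks[[i]]] <-
      shift_field[[g]][region_masks[[i]]] + regions[[i]]$group_shift
  }

  volumes <- vector("list", n)
  for (i in seq_len(n)) {
    dev <- smooth_array(array(stats::rnorm(prod(dims)), dims), sigma_dev)
    dev <- dev / stats::sd(dev) * subject_noise_sd
    field <- bg + dev + shift_field[[subjects$group[i]]]
    field[!mask$voxels] <- empty_space_log
    sm <- smooth_array(field, sigma_vox)
    volumes[[i]] <- jacobian_volume(sm, voxel_size_mm = rep(voxel_size_mm, 3L),
                                    subject_id = subjects$subject_id[i],
                                    stage = "logged")
  }
  volumes <- scale_dataset_unit_interval(volumes, mask = mask)
  volumes <- lapply(volumes, apply_mask, m = mask)

  # behavioral scores tied to driving regions (cycled when scores > regions)
  for (k in seq_along(score_names())) {
    ridx <- (k - 1L) %% length(regions) + 1L
    mean_int <- vapply(volumes, function(v) mean(v$voxels[region_masks[[ridx]]]),
                       numeric(1))
    zint <- (mean_int - mean(mean_int)) / stats::sd(mean_int)
    subjects[[score_names()[k]]] <-
      round(100 - score_effect * zint + stats::rnorm(n, sd = score_noise_sd), 1)
  }

  structure(
    list(subjects = subjects, volumes = volumes, mask = mask,
         truth = regions, dims = dims, seed = seed,
         score_regions = ((seq_along(score_names()) - 1L) %% length(regions)) + 1L),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d cases / %d controls), %s grid, %d planted region(s), seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == "case"),
              sum(x$subjects$group == "control"),
              paste(x$dims, collapse = "x"), length(x$truth), x$seed))
  invisible(x)
}

#' Binary mask of all planted effect regions
#'
#' @param cohort A `cohort` with at least one effect region.
#' @return A [brain_mask()] marking every voxel inside any planted region.
#' @export
planted_truth_mask <- function(cohort) {
  if (length(cohort$truth) < 1L) stop("cohort has no planted regions", call. = FALSE)
  acc <- array(FALSE, cohort$dims)
  for (rg in cohort$truth) acc <- acc | region_indicator(rg, cohort$dims)
  brain_mask(acc)
}

#' Write a cohort to disk
#'
#' Volumes as NIfTI, subject metadata as CSV, and the planted truth
#' (regions + seed) as JSON.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in cohort$volumes) {
    write_volume(v, file.path(dir, paste0(v$subject_id, ".nii.gz")))
  }
  write_volume(cohort$mask, file.path(dir, "mask.nii.gz"))
  utils::write.csv(cohort$subjects, file.path(dir, "subjects.csv"), row.names = FALSE)
  truth <- list(
    seed = cohort$seed, dims = cohort$dims,
    regions = lapply(cohort$truth, function(r) r[c("center", "radius_voxels",
                                                   "group_shift", "target_group")])
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
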