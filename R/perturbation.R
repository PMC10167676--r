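#' Generate random subsampled noise filters
#'
#' Each filter is a contiguous block (default 8 x 8 x 8) at a uniformly
#' random in-bounds origin, filled with i.i.d. standard-normal noise. Only
#' the block is stored; voxels outside it are untouched when the filter is
#' applied.
#'
#' @param dims Image dims the filters will be applied to.
#' @param n_filters Number of filters (default 10000).
#' @param extent Block extent per axis (default `c(8, 8, 8)`).
#' @param seed Integer seed; filter origins and noise are deterministic
#'   given the seed.
#' @return A `noise_filters` object: list with `origins` (n x 3 integer
#'   matrix, 1-based block corners), `noise` (extent-voxels x n matrix),
#'   `extent`, `dims`.
#' @export
make_filters <- function(dims, n_filters = 10000L, extent = c(8L, 8L, 8L),
                         seed = 1L) {
  dims <- as.integer(dims); extent <- as.integer(rep_len(extent, 3L))
  if (any(extent > dims)) stop("filter extent exceeds image dims", call. = FALSE)
  set.seed(seed)
  n_filters <- as.integer(n_filters)
  origins <- cbind(
    sample.int(dims[1] - extent[1] + 1L, n_filters, replace = TRUE),
    sample.int(dims[2] - extent[2] + 1L, n_filters, replace = TRUE),
    sample.int(dims[3] - extent[3] + 1L, n_filters, replace = TRUE)
  )
  if (n_filters == 0L) origins <- matrix(integer(0), 0L, 3L)
  noise <- matrix(stats::rnorm(prod(extent) * n_filters), prod(extent), n_filters)
  structure(list(origins = origins, noise = noise, extent = extent, dims = dims),
            class = "noise_filters")
}

#' @export
print.noise_filters <- function(x, ...) {
  cat(sprintf("<noise_filters> %d filters of %s on a %s grid\n",
              nrow(x$origins), paste(x$extent, collapse = "x"),
              paste(x$dims, collapse = "x")))
  invisible(x)
}

filter_block_ranges <- function(filters, j) {
  o <- filters$origins[j, ]
  lapply(1:3, function(ax) o[ax]:(o[ax] + filters$extent[ax] - 1L))
}

#' Apply one noise filter to a volume
#'
#' Voxelwise addition of the filter's noise block at its origin; all other
#' voxels are unchanged and no clipping is applied.
#'
#' @param x A `jacobian_volume` (or plain 3-D array).
#' @param filters A `noise_filters` object.
#' @param j Filter index.
#' @return The perturbed volume, same type as `x`.
#' @export
perturb <- function(x, filters, j) {
  vox <- if (inherits(x, "jacobian_volume")) x$voxels else x
  if (!all(dim(vox) == filters$dims)) stop("volume and filter dims mismatch", call. = FALSE)
  r <- filter_block_ranges(filters, j)
  blk <- array(filters$noise[, j], filters$extent)
  vox[r[[1]], r[[2]], r[[3]]] <- vox[r[[1]], r[[2]], r[[3]]] + blk
  if (inherits(x, "jacobian_volume")) { x$voxels <- vox; x } else vox
}

#' Signed classification error of a perturbation
#'
#' `e = y_star - y_perturbed`: positive when a case's probability dropped
#' under perturbation (the region supported the case classification),
#' negative when a control's probability rose.
#'
#' @param y_star Base probability of the unperturbed image, in \[0, 1\].
#' @param y_perturbed Probability after perturbation, in \[0, 1\].
#' @return The signed difference.
#' @export
classification_error <- function(y_star, y_perturbed) {
  if (any(y_star < 0 | y_star > 1 | y_perturbed < 0 | y_perturbed > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  y_star - y_perturbed
}

#' Per-subject sensitivity map
#'
#' For every filter: perturb the subject's volume, encode it, classify the
#' latent, and score the signed probability change against the subject's
#' base probability. The error is added uniformly to every voxel of the
#' filter's block in the accumulator and visit counts are incremented; the
#' normalized map divides accumulated error by visit count (zero where a
#' voxel was never visited).
#'
#' @param x A processed `jacobian_volume`.
#' @param y_star Base probability `predict(encode(x))` of the unperturbed
#'   volume (recomputed if `NULL`).
#' @param filters A [make_filters()] object.
#' @param encoder An `ae_params` (or `ae_fit`).
#' @param classifier A `cnn_params` (or `cnn_fit`).
#' @param chunk Number of perturbed volumes evaluated per forward pass.
#' @return A `sensitivity_map`: list with `accum`, `visits`, `normalized`
#'   3-D arrays and `subject_id`, `y_star`.
#' @details The three kernel-2/stride-2 encoder stages make every latent
#'   voxel depend on exactly one 8 x 8 x 8 input block, so a filter
#'   perturbs at most a 2 x 2 x 2 window of latent voxels. Only that window
#'   is re-encoded per filter (the rest of the latent grid is reused from
#'   the unperturbed volume), which gives identical results to re-encoding
#'   the whole volume at a fraction of the cost; the equivalence is
#'   asserted in the test-suite.
#' @export
sensitivity_map <- function(x, y_star = NULL, filters, encoder, classifier,
                            chunk = 64L) {
  if (inherits(encoder, "ae_fit")) encoder <- encoder$params
  if (inherits(classifier, "cnn_fit")) classifier <- classifier$params
  n_f <- nrow(filters$origins)
  if (n_f < 1L) stop("empty filter list", call. = FALSE)
  dims <- dim(x$voxels)
  z0 <- ae_encode_fwd(encoder, array(x$voxels, c(dims, 1L, 1L)))$z
  if (is.null(y_star)) {
    y_star <- as.numeric(cnn_fwd(classifier, z0, training = FALSE)$prob)
  }
  ldims <- dim(z0)[1:3]
  wb <- pmin(ldims, (filters$extent - 1L) %/% 8L + 2L)  # latent window blocks
  win_in <- 8L * wb
  # latent window start per filter and axis
  bs <- sapply(1:3, function(ax) {
    li_min <- (filters$origins[, ax] - 1L) %/% 8L + 1L
    pmax(1L, pmin(li_min, ldims[ax] - wb[ax] + 1L))
  })
  if (n_f == 1L) bs <- matrix(bs, 1L)
  errors <- numeric(n_f)
  n_lat <- dim(z0)[4]
  for (s in seq(1L, n_f, by = chunk)) {
    idx <- s:min(n_f, s + chunk - 1L)
    nb <- length(idx)
    subb <- array(0, c(win_in, 1L, nb))
    zb <- array(z0, c(ldims, n_lat, nb))
    for (k in seq_len(nb)) {
      j <- idx[k]
      i0 <- 8L * (bs[j, ] - 1L)
      rx <- (i0[1] + 1L):(i0[1] + win_in[1])
      ry <- (i0[2] + 1L):(i0[2] + win_in[2])
      rz <- (i0[3] + 1L):(i0[3] + win_in[3])
      sub <- x$voxels[rx, ry, rz]
      o <- filters$origins[j, ] - i0
      blk <- array(filters$noise[, j], filters$extent)
      # clip the noise block to the window (voxels beyond the encoder's
      # cropped tail never reach a latent voxel in the full pass either)
      kx <- seq_len(min(filters$extent[1], win_in[1] - o[1] + 1L))
      ky <- seq_len(min(filters$extent[2], win_in[2] - o[2] + 1L))
      kz <- seq_len(min(filters$extent[3], win_in[3] - o[3] + 1L))
      sub[o[1] + kx - 1L, o[2] + ky - 1L, o[3] + kz - 1L] <-
        sub[o[1] + kx - 1L, o[2] + ky - 1L, o[3] + kz - 1L] + blk[kx, ky, kz]
      subb[, , , 1L, k] <- sub
    }
    zsub <- ae_encode_fwd(encoder, subb)$z
    for (k in seq_len(nb)) {
      j <- idx[k]
      lx <- bs[j, 1]:(bs[j, 1] + wb[1] - 1L)
      ly <- bs[j, 2]:(bs[j, 2] + wb[2] - 1L)
      lz <- bs[j, 3]:(bs[j, 3] + wb[3] - 1L)
      zb[lx, ly, lz, , k] <- zsub[, , , , k]
    }
    probs <- cnn_fwd(classifier, zb, training = FALSE)$prob
    errors[idx] <- classification_error(rep(y_star, nb), probs)
  }
  accum <- array(0, dims)
  visits <- array(0L, dims)
  for (j in seq_len(n_f)) {
    r <- filter_block_ranges(filters, j)
    accum[r[[1]], r[[2]], r[[3]]] <- accum[r[[1]], r[[2]], r[[3]]] + errors[j]
    visits[r[[1]], r[[2]], r[[3]]] <- visits[r[[1]], r[[2]], r[[3]]] + 1L
  }
  normalized <- array(0, dims)
  vis <- visits > 0L
  normalized[vis] <- accum[vis] / visits[vis]
  structure(
    list(accum = accum, visits = visits, normalized = normalized,
         subject_id = x$subject_id, y_star = y_star, errors = errors),
    class = "sensitivity_map"
  )
}

#' @export
print.sensitivity_map <- function(x, ...) {
  cat(sprintf("<sensitivity_map> %s  max |normalized| %.3g, coverage %.1f%%\n",
              x$subject_id, max(abs(x$normalized)),
              100 * mean(x$visits > 0)))
  invisible(x)
}

#' Cohort sensitivity maps
#'
#' Computes a [sensitivity_map()] for every subject with a shared filter
#' set.
#'
#' @param volumes List of processed `jacobian_volume`s.
#' @param filters,encoder,classifier See [sensitivity_map()].
#' @param chunk Encoding batch size.
#' @return List of `sensitivity_map`s.
#' @export
cohort_sensitivity_maps <- function(volumes, filters, encoder, classifier,
                                    chunk = 64L) {
  lapply(volumes, sensitivity_map, y_star = NULL, filters = filters,
         encoder = encoder, classifier = classifier, chunk = chunk)
}

#' Group-average importance maps
#'
#' Voxelwise arithmetic means of normalized sensitivity maps within cases
#' and within controls.
#'
#' @param maps List of `sensitivity_map`s.
#' @param labels Group labels aligned with `maps` (`"case"`/`"control"` or
#'   binary).
#' @return List with `case_mean_map`, `control_mean_map` (3-D arrays).
#' @export
group_importance <- function(maps, labels) {
  y <- normalize_labels(labels)
  if (sum(y == 1L) < 1L || sum(y == 0L) < 1L) {
    stop("each group needs at least one subject", call. = FALSE)
  }
  mean_of <- function(which) {
    acc <- array(0, dim(maps[[1]]$normalized))
    for (i in which) acc <- acc + maps[[i]]$normalized
    acc / length(which)
  }
  list(case_mean_map = mean_of(which(y == 1L)),
       control_mean_map = mean_of(which(y == 0L)))
}

# 26-connected component labeling by BFS flood fill
label_components_26 <- function(bin) {
  dims <- dim(bin)
  labels <- array(0L, dims)
  idx_lin <- which(bin)
  if (length(idx_lin) == 0L) return(labels)
  coords <- arrayInd(idx_lin, dims)
  lab <- 0L
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, ]
  for (start in idx_lin) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue) > 0L) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      p <- arrayInd(cur, dims)[1, ]
      nb <- sweep(offs, 2L, p, `+`)
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) + dims[1] * dims[2] * (nb[, 3] - 1L)
      new <- lin[bin[lin] & labels[lin] == 0L]
      if (length(new) > 0L) {
        labels[new] <- lab
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Extract regions of interest from a group importance map
#'
#' Thresholds `|mean_map| >= threshold` (probability-change units; the
#' default 0.25 corresponds to a 25-percentage-point change in
#' classification probability), labels 26-connected components, drops
#' components smaller than `min_size`, and records each component's sign.
#'
#' @param mean_map A 3-D group importance map.
#' @param threshold Absolute probability-change threshold (default 0.25).
#' @param min_size Minimum component size in voxels (default 27).
#' @return A tibble with one row per ROI: `label`, `sign`
#'   (`"case_important"` for positive map values), `size`, `centroid_x/y/z`,
#'   and a list-column `voxels` of linear voxel indices.
#' @export
extract_rois <- function(mean_map, threshold = 0.25, min_size = 27L) {
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)", call. = FALSE)
  dims <- dim(mean_map)
  bin <- abs(mean_map) >= threshold
  labs <- label_components_26(bin)
  out <- list()
  for (lab in seq_len(max(labs))) {
    vox <- which(labs == lab)
    if (length(vox) < min_size) next
    co <- arrayInd(vox, dims)
    sgn <- if (mean(mean_map[vox]) >= 0) "case_important" else "control_important"
    out[[length(out) + 1L]] <- tibble::tibble(
      label = sprintf("roi_%02d", length(out) + 1L),
      sign = sgn, size = length(vox),
      centroid_x = mean(co[, 1]), centroid_y = mean(co[, 2]),
      centroid_z = mean(co[, 3]),
      voxels = list(vox)
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(label = character(0), sign = character(0),
                          size = integer(0), centroid_x = numeric(0),
                          centroid_y = numeric(0), centroid_z = numeric(0),
                          voxels = list()))
  }
  dplyr::bind_rows(out)
}

#' Mean Jacobian value over an ROI
#'
#' @param volume A `jacobian_volume`.
#' @param roi One row of [extract_rois()] output (or any list with a
#'   `voxels` element of linear indices).
#' @return Arithmetic mean of the volume over the ROI's voxels.
#' @export
roi_mean_jacobian <- function(volume, roi) {
  vox <- if (is.list(roi$voxels) && !is.numeric(roi$voxels)) roi$voxels[[1]] else roi$voxels
  if (length(vox) == 0L) stop("empty ROI", call. = FALSE)
  if (max(vox) > length(volume$voxels)) stop("ROI voxels outside volume", call. = FALSE)
  mean(volume$voxels[vox])
}

#' Per-subject mean Jacobian table for a set of ROIs
#'
#' @param volumes List of `jacobian_volume`s.
#' @param rois Output of [extract_rois()].
#' @return Tibble `subject_id` x one column per ROI label.
#' @export
roi_subject_table <- function(volumes, rois) {
  out <- tibble::tibble(
    subject_id = vapply(volumes, function(v) v$subject_id, character(1))
  )
  for (i in seq_len(nrow(rois))) {
    out[[rois$label[i]]] <- vapply(volumes, roi_mean_jacobian,
                                   numeric(1), roi = rois[i, ])
  }
  out
}
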