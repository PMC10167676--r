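test_that("filter origins enumerate all valid in-bounds positions uniformly", {
  f0 <- make_filters(c(10L, 8L, 8L), n_filters = 0L, seed = 1)
  expect_identical(nrow(f0$origins), 0L)

  # 1-D analogue: extent 8 along a dim of 10 leaves exactly origins 1..3
  f <- make_filters(c(10L, 8L, 8L), n_filters = 1000L, seed = 2)
  expect_setequal(unique(f$origins[, 1]), 1:3)
  expect_true(all(f$origins[, 2] == 1L) && all(f$origins[, 3] == 1L))
  counts <- table(f$origins[, 1])
  expect_true(all(counts > 1000 / 3 * 0.7))

  expect_error(make_filters(c(6L, 8L, 8L), 10L), "exceeds")
})

test_that("filter noise is standard normal in aggregate", {
  f <- make_filters(c(16L, 16L, 16L), n_filters = 100L, seed = 3)
  vals <- as.vector(f$noise)  # 51200 draws
  expect_lt(abs(mean(vals)), 0.02)
  expect_lt(abs(stats::sd(vals) - 1), 0.02)
})

test_that("perturbation is local, additive and conservative", {
  f <- make_filters(c(12L, 12L, 12L), n_filters = 5L, extent = c(2L, 2L, 2L), seed = 4)
  x <- grid_volume(c(12L, 12L, 12L), seed = 5, stage = "scaled")

  fz <- f; fz$noise[] <- 0
  expect_identical(perturb(x, fz, 1)$voxels, x$voxels)

  f1 <- f; f1$noise[, 2] <- 1; f1$origins[2, ] <- c(1L, 1L, 1L)
  zero <- grid_volume(c(12L, 12L, 12L), values = 0)
  pz <- perturb(zero, f1, 2)
  expect_identical(sum(pz$voxels == 1), 8L)
  expect_identical(sum(pz$voxels != 0), 8L)

  for (j in 1:5) {
    pj <- perturb(x, f, j)
    expect_equal(sum(pj$voxels) - sum(x$voxels), sum(f$noise[, j]), tolerance = 1e-10)
  }
})

test_that("classification error is the signed probability drop", {
  expect_equal(classification_error(1, 0.6), 0.4)
  expect_equal(classification_error(0, 0.3), -0.3)
  expect_equal(classification_error(0.7, 0.7), 0)
  expect_error(classification_error(1.2, 0.5), "\\[0, 1\\]")
})

test_that("sensitivity maps follow the accumulate-and-normalize contract", {
  set.seed(6)
  coh <- small_cohort(seed = 17, n = 4)
  sp <- list(train_ids = 1:6, test_ids = 7:8)
  ae <- train_autoencoder(coh$volumes, sp, steps = 60L, batch_size = 4L,
                          latent_channels = 4L, hidden_channels = c(2L, 3L),
                          eval_every = 30L, seed = 17)
  set.seed(18)
  cp <- build_classifier(ae$params$latent_dims, latent_channels = 4L,
                         conv_channels = 2L, fc_units = 4L)
  x <- coh$volumes[[1]]

  # constant classifier (zero weights): all errors zero, map identically zero
  cp0 <- cp
  for (nm in names(cp0$params)) cp0$params[[nm]][] <- 0
  f <- make_filters(coh$dims, n_filters = 20L, seed = 19)
  m0 <- sensitivity_map(x, NULL, f, ae$params, cp0)
  expect_true(all(m0$normalized == 0))

  # single filter: normalized equals the hand-computed error inside the
  # block and zero outside
  f1 <- make_filters(coh$dims, n_filters = 1L, seed = 20)
  m1 <- sensitivity_map(x, NULL, f1, ae$params, cp)
  y_star <- predict_probability(cp, encode(ae$params, x))$probability
  xp <- perturb(x, f1, 1)
  y_pert <- predict_probability(cp, encode(ae$params, xp))$probability
  e <- y_star - y_pert
  r <- dbmnet:::filter_block_ranges(f1, 1)
  expect_equal(unique(as.vector(m1$normalized[r[[1]], r[[2]], r[[3]]])), e,
               tolerance = 1e-12)
  out_vals <- m1$normalized; out_vals[r[[1]], r[[2]], r[[3]]] <- 0
  expect_true(all(out_vals == 0))

  # conservation: sum(accum) equals sum over filters of error * block volume
  m <- sensitivity_map(x, NULL, f, ae$params, cp)
  expect_equal(sum(m$accum), sum(m$errors) * prod(f$extent), tolerance = 1e-8)
  expect_true(all(abs(m$normalized) <= 1))
  expect_true(all(m$normalized[m$visits == 0] == 0))

  expect_error(sensitivity_map(x, NULL, make_filters(coh$dims, 0L, seed = 1),
                               ae$params, cp),
               "empty")

  # windowed re-encoding equals the naive full re-encode for every filter
  err_ref <- vapply(seq_len(nrow(f$origins)), function(j) {
    y_star - predict_probability(cp, encode(ae$params, perturb(x, f, j)))$probability
  }, numeric(1))
  expect_equal(m$errors, err_ref, tolerance = 1e-12)
})

test_that("group importance maps are voxelwise means per group", {
  dims <- c(4L, 4L, 4L)
  mk <- function(vals) structure(list(normalized = array(vals, dims)),
                                 class = "sensitivity_map")
  m <- array(rnorm(64), dims)
  gi <- group_importance(list(mk(m), mk(m)), c("case", "control"))
  expect_equal(gi$case_mean_map, m)
  expect_equal(gi$control_mean_map, m)

  gi2 <- group_importance(list(mk(m), mk(-m), mk(0)), c("case", "case", "control"))
  expect_equal(gi2$case_mean_map, array(0, dims))

  set.seed(7)
  maps <- lapply(1:5, function(i) mk(rnorm(64)))
  labs <- c(1, 1, 1, 0, 0)
  gi3 <- group_importance(maps, labs)
  acc <- array(0, dims)
  for (i in 1:3) acc <- acc + maps[[i]]$normalized
  expect_equal(gi3$case_mean_map, acc / 3)

  expect_error(group_importance(list(mk(m)), c("case")), "at least one")
})

test_that("ROI extraction thresholds, labels 26-connected components and records sign", {
  dims <- c(12L, 12L, 12L)
  expect_identical(nrow(extract_rois(array(0, dims))), 0L)

  one <- array(0, dims); one[3:6, 3:6, 3:6] <- 0.3
  r1 <- extract_rois(one, min_size = 8L)
  expect_identical(nrow(r1), 1L)
  expect_identical(r1$size, 64L)
  expect_identical(r1$sign, "case_important")
  expect_setequal(r1$voxels[[1]], which(one >= 0.25))

  # two cubes touching only at a corner merge under 26-connectivity;
  # igraph components on the voxel adjacency graph is the oracle
  two <- array(0, dims)
  two[3:5, 3:5, 3:5] <- 0.3
  two[6:8, 6:8, 6:8] <- -0.3
  vox <- which(abs(two) >= 0.25)
  co <- arrayInd(vox, dims)
  adj <- which(as.matrix(stats::dist(co, method = "maximum")) <= 1 &
                 upper.tri(matrix(0, length(vox), length(vox))), arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(vox) - igraph::vcount(g)))
  n_oracle <- igraph::components(g)$no
  r2 <- extract_rois(two, min_size = 20L)
  expect_equal(nrow(r2), n_oracle)

  # separated cubes of opposite sign give two ROIs with correct signs
  sep <- array(0, dims)
  sep[2:4, 2:4, 2:4] <- 0.4
  sep[8:10, 8:10, 8:10] <- -0.4
  r3 <- extract_rois(sep, min_size = 20L)
  expect_identical(nrow(r3), 2L)
  expect_setequal(r3$sign, c("case_important", "control_important"))
})

test_that("ROI mean Jacobian values match a loop-based mean", {
  v <- grid_volume(c(6L, 6L, 6L), values = 0.7)
  roi <- tibble::tibble(label = "r1", voxels = list(c(1L, 5L, 9L)))
  expect_equal(roi_mean_jacobian(v, roi), 0.7)

  v2 <- grid_volume(c(6L, 6L, 6L), seed = 8)
  v2$voxels[1] <- 0.2; v2$voxels[2] <- 0.4
  roi2 <- tibble::tibble(label = "r2", voxels = list(1:2))
  expect_equal(roi_mean_jacobian(v2, roi2), 0.3)

  set.seed(9)
  vox <- sample(216, 20)
  acc <- 0
  for (k in vox) acc <- acc + v2$voxels[k]
  expect_equal(roi_mean_jacobian(v2, tibble::tibble(voxels = list(vox))), acc / 20)

  tab <- roi_subject_table(list(v, v2), dplyr::bind_rows(roi, roi2))
  expect_identical(dim(tab), c(2L, 3L))
})

test_that("10,000 filters cover most of the full-size grid", {
  dims <- c(121L, 145L, 121L)
  f <- make_filters(dims, n_filters = 10000L, seed = 10)
  visits <- array(0L, dims)
  for (j in seq_len(10000L)) {
    o <- f$origins[j, ]
    visits[o[1]:(o[1] + 7L), o[2]:(o[2] + 7L), o[3]:(o[3] + 7L)] <-
      visits[o[1]:(o[1] + 7L), o[2]:(o[2] + 7L), o[3]:(o[3] + 7L)] + 1L
  }
  # interior voxels (full 512 covering origins) expect ~2.9 visits each,
  # giving Poisson coverage of about 94%; edge voxels see fewer origins
  interior <- visits[8:114, 8:138, 8:114]
  expect_gte(mean(interior > 0L), 0.90)
})
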