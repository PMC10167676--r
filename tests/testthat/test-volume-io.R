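test_that("NIfTI round trip preserves voxel data, dims and voxel size", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  v <- grid_volume(c(4L, 4L, 4L), values = 1)
  write_volume(v, tmp)
  back <- read_volume(tmp)
  expect_equal(back$voxels, v$voxels)

  # a specific voxel written and recovered under the fixed (x, y, z)
  # 0-based convention: voxel (2,3,1) is R index [3,4,2]
  v2 <- grid_volume(c(6L, 6L, 6L), seed = 1, voxel_size_mm = c(2, 2, 2))
  v2$voxels[3, 4, 2] <- 7.5
  tmp2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v2, tmp2)
  back2 <- read_volume(tmp2)
  expect_identical(back2$voxels[3, 4, 2], 7.5)
  expect_equal(back2$voxels, v2$voxels)
  expect_equal(back2$voxel_size_mm, c(2, 2, 2))
})

test_that("the full template grid reports its header dims", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  v <- jacobian_volume(array(0, c(121L, 145L, 121L)))
  write_volume(v, tmp)
  expect_identical(dim(read_volume(tmp)), c(121L, 145L, 121L))
})

test_that("read_volume raises distinct named failures", {
  expect_error(read_volume("no/such/file.nii"), "not found")
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(3, 3, 3, 2))), tmp)
  expect_error(read_volume(tmp), "3-D")
  bad <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  suppressWarnings(expect_error(read_volume(bad), "unreadable|NIfTI"))
})

test_that("gaussian smoothing leaves constants unchanged and matches the analytic kernel", {
  v <- grid_volume(c(12L, 12L, 12L), values = 3.25)
  sm <- gaussian_smooth(v, 8)
  expect_equal(sm$voxels, v$voxels, tolerance = 1e-10)
  expect_identical(sm$stage, "smoothed")

  # FWHM -> sigma conversion constant
  expect_equal(8 / fwhm_to_sigma_factor(), 3.39727, tolerance = 1e-4)

  # impulse response equals the separable analytic Gaussian
  dims <- c(33L, 33L, 33L)
  imp <- jacobian_volume(array(0, dims))
  imp$voxels[17, 17, 17] <- 1
  resp <- gaussian_smooth(imp, 8)$voxels
  s <- 8 / fwhm_to_sigma_factor()
  g1 <- function(d) exp(-d^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
  d1 <- g1(seq_len(33) - 17)
  analytic <- outer(outer(d1, d1), d1)
  dim(analytic) <- dims
  expect_lt(max(abs(resp - analytic)), 1e-6)
})

test_that("smoothing validates its inputs", {
  v <- grid_volume(c(8L, 8L, 8L), seed = 2)
  expect_error(gaussian_smooth(v, 0), "positive")
  v$voxel_size_mm <- c(NA, 1, 1)
  expect_error(gaussian_smooth(v, 8), "voxel size")
})

test_that("log transform follows the natural log within the mask", {
  v <- grid_volume(c(2L, 2L, 2L), values = c(1, exp(1), 0.5, 2, 1, 1, 1, 1))
  lt <- log_transform(v)
  expect_equal(lt$voxels[1, 1, 1], 0)
  expect_equal(lt$voxels[2, 1, 1], 1)
  expect_equal(lt$voxels[1, 2, 1], -0.6931, tolerance = 1e-4)
  expect_identical(lt$stage, "logged")

  bad <- grid_volume(c(2L, 2L, 2L), values = c(1, -0.1, 1, 1, 1, 1, 1, 1))
  expect_error(log_transform(bad), "non-positive")
})

test_that("unit scaling maps the global dataset range to [0, 1] with one affine", {
  v1 <- grid_volume(c(3L, 1L, 1L), values = c(-1, 0, 1), stage = "logged")
  sc <- scale_dataset_unit_interval(list(v1))
  expect_equal(as.vector(sc[[1]]$voxels), c(0, 0.5, 1))

  # shared affine across volumes: global min in A, max in B
  a <- grid_volume(c(2L, 1L, 1L), values = c(-2, 0), stage = "logged")
  b <- grid_volume(c(2L, 1L, 1L), values = c(0, 2), stage = "logged")
  sc2 <- scale_dataset_unit_interval(list(a, b))
  expect_equal(sc2[[1]]$voxels[2, 1, 1], 0.5)
  expect_equal(sc2[[2]]$voxels[1, 1, 1], 0.5)

  # property: outputs attain 0 and 1 exactly; rescaling is idempotent
  set.seed(3)
  vols <- lapply(1:4, function(i) grid_volume(c(5L, 5L, 5L), seed = i, stage = "logged"))
  out <- scale_dataset_unit_interval(vols)
  allv <- unlist(lapply(out, function(v) v$voxels))
  expect_equal(min(allv), 0)
  expect_equal(max(allv), 1)
  again <- scale_dataset_unit_interval(out)
  expect_equal(lapply(again, `[[`, "voxels"), lapply(out, `[[`, "voxels"))

  expect_error(scale_dataset_unit_interval(list(grid_volume(c(2L, 2L, 2L), values = 1))),
               "degenerate")
})

test_that("masking zeroes out-of-mask voxels and conserves in-mask values", {
  v <- grid_volume(c(4L, 4L, 4L), seed = 5)
  all_in <- brain_mask(array(1, c(4, 4, 4)))
  expect_equal(apply_mask(v, all_in)$voxels, v$voxels)

  expect_error(brain_mask(array(0, c(4, 4, 4))), "at least one")

  half <- array(0, c(4, 4, 4)); half[1:2, , ] <- 1
  m <- brain_mask(half)
  masked <- apply_mask(v, m)
  expect_equal(sum(masked$voxels), sum(v$voxels[1:2, , ]))
  expect_true(all(masked$voxels[3:4, , ] == 0))

  wrong <- brain_mask(array(1, c(3, 3, 3)))
  expect_error(apply_mask(v, wrong), "mismatch")
})

test_that("the preprocessing chain is deterministic", {
  set.seed(9)
  vols <- lapply(1:3, function(i) grid_volume(c(10L, 10L, 10L), seed = i + 10) )
  vols <- lapply(vols, function(v) { v$voxels <- v$voxels + 0.5; v })
  m <- brain_mask(array(rep(c(1, 0), length.out = 1000), c(10, 10, 10)))
  r1 <- preprocess_volumes(vols, m, fwhm_mm = 4)
  r2 <- preprocess_volumes(vols, m, fwhm_mm = 4)
  expect_identical(lapply(r1, `[[`, "voxels"), lapply(r2, `[[`, "voxels"))
  expect_true(all(vapply(r1, function(v) all(v$voxels >= 0 & v$voxels <= 1), logical(1))))
})
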