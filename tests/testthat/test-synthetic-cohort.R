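test_that("cohorts are bit-identical for the same seed", {
  c1 <- small_cohort(seed = 3, n = 6)
  c2 <- small_cohort(seed = 3, n = 6)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(lapply(c1$volumes, `[[`, "voxels"),
                   lapply(c2$volumes, `[[`, "voxels"))
  c3 <- small_cohort(seed = 4, n = 6)
  expect_false(identical(c1$volumes[[1]]$voxels, c3$volumes[[1]]$voxels))
})

test_that("generated volumes satisfy the processed-volume invariants", {
  coh <- small_cohort(seed = 5, n = 8)
  inm <- coh$mask$voxels
  for (v in coh$volumes[c(1, 8, 16)]) {
    expect_true(all(v$voxels[inm] >= 0 & v$voxels[inm] <= 1))
    expect_true(all(v$voxels[!inm] == 0))
    expect_identical(v$stage, "scaled")
  }
})

test_that("site composition matches requested proportions exactly when divisible", {
  sites <- tibble::tibble(site = c("X", "Y"), prop_cases = c(0.25, 0.75),
                          prop_controls = c(0.5, 0.5))
  coh <- generate_cohort(8, 6, dims = c(16L, 16L, 16L), sites = sites,
                         regions = list(effect_region(c(8, 8, 8), 3, 0.5)),
                         seed = 1)
  tab <- table(coh$subjects$site, coh$subjects$group)
  expect_identical(as.vector(tab[c("X", "Y"), "case"]), c(2L, 6L))
  expect_identical(as.vector(tab[c("X", "Y"), "control"]), c(3L, 3L))

  # default five-site table at the reference size reproduces the
  # over-imbalanced site (22 cases vs 4 controls)
  coh2 <- fixture_cohort()
  tab2 <- table(coh2$subjects$site, coh2$subjects$group)
  expect_identical(as.vector(tab2["E", ]), c(22L, 4L))
})

test_that("planted truth mask equals brute-force ball enumeration", {
  dims <- c(15L, 15L, 15L)
  coh <- generate_cohort(2, 2, dims = dims,
                         regions = list(effect_region(c(8, 8, 8), 3, 0.5)),
                         seed = 2)
  tm <- planted_truth_mask(coh)
  # independent enumeration
  cnt <- 0L
  for (x in 1:15) for (y in 1:15) for (z in 1:15) {
    if ((x - 8)^2 + (y - 8)^2 + (z - 8)^2 <= 9) cnt <- cnt + 1L
  }
  expect_identical(sum(tm$voxels), cnt)

  # two disjoint spheres are additive
  coh2 <- generate_cohort(2, 2, dims = c(24L, 24L, 24L),
                          regions = list(effect_region(c(6, 6, 6), 3, 0.5),
                                         effect_region(c(18, 18, 18), 3, 0.5)),
                          seed = 2)
  expect_identical(sum(planted_truth_mask(coh2)$voxels), 2L * cnt)

  expect_error(effect_region(c(8, 8, 8), 0, 0.5), ">= 1")
  expect_error(generate_cohort(2, 2, dims = c(10L, 10L, 10L),
                               regions = list(effect_region(c(9, 9, 9), 3, 0.5)),
                               seed = 1),
               "fit")
})

test_that("a large planted shift is recovered with the planted sign in every seed", {
  # at 24^3 with radius-3 regions the 8 mm kernel attenuates the shift to
  # ~17% of its nominal value, so "large" here means well above the default
  hits <- 0L
  for (s in 1:20) {
    coh <- small_cohort(seed = 100 + s, n = 8, shift = 2)
    rg <- coh$truth[[1]]  # case-target region
    rm <- dbmnet:::region_indicator(rg, coh$dims)
    mi <- vapply(coh$volumes, function(v) mean(v$voxels[rm]), numeric(1))
    grp <- coh$subjects$group
    if (mean(mi[grp == "case"]) > mean(mi[grp == "control"])) hits <- hits + 1L
  }
  expect_identical(hits, 20L)
})

test_that("a null cohort shows no significant group difference in most seeds", {
  nonsig <- 0L
  for (s in 1:30) {
    coh <- small_cohort(seed = 200 + s, n = 8, shift = 0)
    rg <- coh$truth[[1]]
    rm <- dbmnet:::region_indicator(rg, coh$dims)
    mi <- vapply(coh$volumes, function(v) mean(v$voxels[rm]), numeric(1))
    grp <- coh$subjects$group
    p <- stats::t.test(mi[grp == "case"], mi[grp == "control"])$p.value
    if (p > 0.05) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 25L)
})

test_that("behavioral scores carry the planted negative correlation with their region", {
  ok <- 0L
  for (s in 1:6) {
    coh <- generate_cohort(40, 40, dims = c(24L, 24L, 24L),
                           regions = list(effect_region(c(9, 9, 9), 3, 0.75, "case"),
                                          effect_region(c(16, 16, 16), 3, 0.75, "control")),
                           seed = 300 + s)
    rm <- dbmnet:::region_indicator(coh$truth[[1]], coh$dims)
    mi <- vapply(coh$volumes, function(v) mean(v$voxels[rm]), numeric(1))
    if (stats::cor(coh$subjects$WA, mi) < 0) ok <- ok + 1L
  }
  expect_identical(ok, 6L)
})

test_that("write_cohort emits volumes, metadata and a truth sidecar", {
  dir <- withr::local_tempdir()
  coh <- small_cohort(seed = 6, n = 2)
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "subjects.csv")))
  expect_true(file.exists(file.path(dir, "mask.nii.gz")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  expect_identical(length(list.files(dir, pattern = "^S\\d+\\.nii\\.gz$")), 4L)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_identical(truth$seed, 6L)
})
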