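# Shared fixtures, built lazily and cached for the whole test session.
# The desk-scale cohort and its 2500-step autoencoder are expensive; they
# are computed once and reused by every acceptance block that needs them.

.fx <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fx$cohort)) {
    .fx$cohort <- generate_cohort(96, 96, seed = 42)
  }
  .fx$cohort
}

fixture_split <- function() {
  if (is.null(.fx$split)) {
    .fx$split <- stratified_split(fixture_cohort()$subjects, 0.2, seed = 42)
  }
  .fx$split
}

fixture_ae <- function() {
  if (is.null(.fx$ae)) {
    .fx$ae <- train_autoencoder(fixture_cohort()$volumes, fixture_split(),
                                steps = 2500L, seed = 42)
  }
  .fx$ae
}

fixture_latents <- function() {
  if (is.null(.fx$latents)) {
    .fx$latents <- encode_batch(fixture_ae()$params, fixture_cohort()$volumes)
  }
  .fx$latents
}

# classifier trained on the fixture latents over the fixture split
fixture_cnn <- function() {
  if (is.null(.fx$cnn)) {
    coh <- fixture_cohort()
    .fx$cnn <- train_classifier(fixture_latents(), coh$subjects$group,
                                fixture_split(), seed = 42)
  }
  .fx$cnn
}

# stratified 48 + 48 subset of the fixture cohort for the method benchmark
fixture_subset <- function() {
  if (is.null(.fx$subset)) {
    coh <- fixture_cohort()
    cells <- split(seq_len(nrow(coh$subjects)),
                   list(coh$subjects$site, coh$subjects$group), drop = TRUE)
    idx <- sort(unlist(lapply(cells, function(ids) ids[seq_len(ceiling(length(ids) / 2))])))
    sub <- coh
    sub$subjects <- coh$subjects[idx, ]
    sub$volumes <- coh$volumes[idx]
    .fx$subset <- sub
  }
  .fx$subset
}

# a small cohort for fast unit tests (latent 3x3x3 supports the classifier)
small_cohort <- function(seed = 7, n = 12, shift = 0.75) {
  generate_cohort(n, n, dims = c(24L, 24L, 24L),
                  regions = list(
                    effect_region(c(9, 9, 9), 3, shift, "case"),
                    effect_region(c(16, 16, 16), 3, shift, "control")
                  ),
                  seed = seed)
}

# deterministic volume helper
grid_volume <- function(dims, values = NULL, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  v <- if (is.null(values)) array(stats::runif(prod(dims)), dims) else array(values, dims)
  jacobian_volume(v, ...)
}
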