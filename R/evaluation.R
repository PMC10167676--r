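#' Confusion-matrix metrics at a probability threshold
#'
#' Accuracy (fraction correct), precision `TP / (TP + FP)` and recall
#' `TP / (TP + FN)` with `"case"` (label 1) as the positive class.
#' Precision is `NA` (flagged) when no positive predictions are made.
#'
#' @param probabilities Predicted case probabilities.
#' @param labels Binary ground-truth labels.
#' @param threshold Hard-label threshold (default 0.5).
#' @return A one-row tibble: `accuracy`, `precision`, `recall`, `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(probabilities, labels, threshold = 0.5) {
  y <- normalize_labels(labels)
  if (length(probabilities) != length(y)) stop("length mismatch", call. = FALSE)
  pred <- as.integer(probabilities >= threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  tibble::tibble(
    accuracy = (tp + tn) / length(y),
    precision = if (tp + fp == 0L) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0L) NA_real_ else tp / (tp + fn),
    tp = tp, fp = fp, fn = fn, tn = tn
  )
}

#' ROC curve and AUC
#'
#' AUC equals the probability that a randomly chosen case outranks a
#' randomly chosen control (ties count one half); the curve sweeps all
#' thresholds.
#'
#' @param probabilities Predicted case probabilities (any scores).
#' @param labels Binary labels; both classes must be present.
#' @return A list with `auc` and `roc_curve` (tibble `fpr`, `tpr`,
#'   monotone non-decreasing in both coordinates).
#' @export
roc_auc <- function(probabilities, labels) {
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  r <- pROC::roc(response = y, predictor = as.numeric(probabilities),
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  curve <- tibble::tibble(fpr = rev(1 - r$specificities),
                          tpr = rev(r$sensitivities))
  list(auc = as.numeric(pROC::auc(r)), roc_curve = curve)
}

#' Repeated-split evaluation of the AE + CNN classifier
#'
#' Over `n_splits` site-stratified splits the CNN is retrained from random
#' initialisation on the frozen autoencoder's latents and evaluated on the
#' held-out subjects; the autoencoder itself is trained once beforehand and
#' not refitted. Also returns, per subject, the number of test-set
#' appearances and the median held-out case probability across them.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param ae_fit A trained [train_autoencoder()] fit.
#' @param n_splits Number of splits (default 100; must be >= 2).
#' @param test_ratio Held-out fraction (default 0.2).
#' @param per_site_ratio Optional named vector of per-site test ratios
#'   overriding `test_ratio`, used to keep every subject's expected number
#'   of test appearances within a target band when site sizes are very
#'   unequal.
#' @param cnn_args List of extra arguments for [train_classifier()].
#' @param seed Integer seed; per-split seeds are derived from it.
#' @return An `eval_result`: list with `metrics` (tibble of per-split
#'   `accuracy`, `precision`, `recall`, `auc`), `subject_summary` (tibble
#'   `subject_id`, `group`, `n_test_appearances`, `median_probability`),
#'   and `roc_curves`.
#' @export
repeated_splits <- function(cohort, ae_fit, n_splits = 100L, test_ratio = 0.2,
                            per_site_ratio = NULL, cnn_args = list(),
                            seed = 1L) {
  if (n_splits < 2L) stop("`n_splits` must be >= 2", call. = FALSE)
  y <- normalize_labels(cohort$subjects$group)
  latents <- encode_batch(ae_fit$params, volumes_to_batch(cohort$volumes))
  n <- nrow(cohort$subjects)
  prob_store <- vector("list", n)
  metrics <- list(); curves <- list()
  for (s in seq_len(n_splits)) {
    sp_seed <- seed * 1000L + s
    sp <- if (is.null(per_site_ratio)) {
      stratified_split(cohort$subjects, test_ratio, seed = sp_seed)
    } else {
      per_site_stratified_split(cohort$subjects, per_site_ratio, seed = sp_seed)
    }
    fit <- do.call(train_classifier,
                   c(list(latents, y, sp, seed = sp_seed), cnn_args))
    pr <- predict_probability(fit, latents[, , , , sp$test_ids, drop = FALSE])
    m <- confusion_metrics(pr$probability, y[sp$test_ids])
    if (length(unique(y[sp$test_ids])) == 2L) {
      roc <- roc_auc(pr$probability, y[sp$test_ids])
      m$auc <- roc$auc
      curves[[s]] <- dplyr::mutate(roc$roc_curve, split_id = s)
    } else {
      m$auc <- NA_real_  # flagged: single-class test partition
    }
    m$split_id <- s
    metrics[[s]] <- m
    for (k in seq_along(sp$test_ids)) {
      i <- sp$test_ids[k]
      prob_store[[i]] <- c(prob_store[[i]], pr$probability[k])
    }
  }
  subject_summary <- tibble::tibble(
    subject_id = cohort$subjects$subject_id,
    group = cohort$subjects$group,
    site = cohort$subjects$site,
    n_test_appearances = vapply(prob_store, length, integer(1)),
    median_probability = vapply(prob_store, function(p) {
      if (length(p) == 0L) NA_real_ else stats::median(p)
    }, numeric(1))
  )
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         subject_summary = subject_summary,
         roc_curves = dplyr::bind_rows(curves), n_splits = n_splits,
         seed = seed),
    class = "eval_result"
  )
}

# stratified split with a different test ratio per site
per_site_stratified_split <- function(subjects, per_site_ratio, seed) {
  set.seed(seed)
  n <- nrow(subjects)
  strata <- split(seq_len(n), list(subjects$site, subjects$group), drop = TRUE)
  test_ids <- integer(0)
  for (nm in names(strata)) {
    ids <- strata[[nm]]
    site <- subjects$site[ids[1]]
    ratio <- per_site_ratio[[site]]
    k <- min(length(ids), floor(ratio * length(ids) + 0.5))
    if (k > 0L) test_ids <- c(test_ids, sample(ids, k))
  }
  test_ids <- sort(test_ids)
  structure(list(train_ids = setdiff(seq_len(n), test_ids),
                 test_ids = test_ids, seed = seed, test_ratio = NA_real_),
            class = "split_plan")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(
    "<eval_result> %d splits: mean accuracy %.3f, mean AUC %.3f\n",
    x$n_splits, mean(x$metrics$accuracy), mean(x$metrics$auc)))
  invisible(x)
}

#' Paired t-test of per-split accuracies between two methods
#'
#' Both accuracy vectors must come from the identical splits. Cohen's d for
#' paired data is `mean(diff) / sd(diff)`.
#'
#' @param acc_a,acc_b Equal-length (>= 3) per-split accuracy vectors.
#' @return A one-row tibble: `t`, `p`, `cohens_d`, `mean_diff`,
#'   `degenerate` (TRUE when the differences have zero variance, in which
#'   case `t` and `p` are NA).
#' @export
paired_accuracy_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 3L) {
    stop("need equal-length vectors of at least 3 paired accuracies", call. = FALSE)
  }
  d <- acc_a - acc_b
  if (stats::sd(d) < .Machine$double.eps^0.5) {
    return(tibble::tibble(t = NA_real_, p = NA_real_,
                          cohens_d = if (all(d == 0)) 0 else NA_real_,
                          mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(acc_a, acc_b, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), p = tt$p.value,
                 cohens_d = mean(d) / stats::sd(d), mean_diff = mean(d),
                 degenerate = FALSE)
}

#' Ordinary least squares regression with per-coefficient t tests
#'
#' Least-squares fit with intercept via `stats::lm`. Character/factor
#' predictors (e.g. research site) enter as indicator contrasts with the
#' most frequent level as reference.
#'
#' @param data A data frame.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor columns.
#' @return A list with `coefficients` (tibble `term`, `estimate`,
#'   `std_error`, `t`, `p`), `r_squared`, `f`, `df`, and the underlying
#'   `lm` fit.
#' @export
ols_regression <- function(data, response, predictors) {
  if (nrow(data) <= length(predictors) + 1L) {
    stop("need n > p + 1 observations", call. = FALSE)
  }
  df <- data[c(response, predictors)]
  for (p in predictors) {
    if (is.character(df[[p]]) || is.factor(df[[p]])) {
      tab <- sort(table(df[[p]]), decreasing = TRUE)
      df[[p]] <- factor(df[[p]], levels = names(tab))
    }
  }
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design", call. = FALSE)
  sm <- summary(fit)
  co <- sm$coefficients
  list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = as.numeric(co[, 1]),
      std_error = as.numeric(co[, 2]), t = as.numeric(co[, 3]),
      p = as.numeric(co[, 4])
    ),
    r_squared = sm$r.squared,
    f = unname(sm$fstatistic[1]),
    df = unname(sm$fstatistic[2:3]),
    fit = fit
  )
}

#' Pearson correlation with p-value and Fisher-z confidence interval
#'
#' @param x,y Numeric vectors (n >= 3, finite, non-constant).
#' @return A one-row tibble: `r`, `p`, `ci_lo`, `ci_hi`, `n`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) stop("need n >= 3 paired values", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", conf.level = 0.95)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value,
                 ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
                 n = length(x))
}
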