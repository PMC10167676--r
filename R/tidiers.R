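#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang %||%
NULL

#' Tidy the training trace of an autoencoder fit
#'
#' @param x An `ae_fit`.
#' @param ... Unused.
#' @return A long tibble: `step`, `partition`, `loss`.
#' @export
tidy.ae_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, c("train_loss", "test_loss"),
                      names_to = "partition", values_to = "loss") |>
    dplyr::mutate(partition = sub("_loss$", "", .data$partition))
}

#' @rdname tidy.ae_fit
#' @return For `glance`: one row with `steps`, `final_train_loss`,
#'   `final_test_loss`, `latent_compression`.
#' @export
glance.ae_fit <- function(x, ...) {
  tibble::tibble(
    steps = max(x$trace$step),
    final_train_loss = x$trace$train_loss[nrow(x$trace)],
    final_test_loss = x$final_test_loss,
    latent_compression = latent_compression_fraction(x$params)
  )
}

#' Tidy the training trace of a classifier fit
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @return A long tibble: `step`, `partition`, `loss`.
#' @export
tidy.cnn_fit <- function(x, ...) {
  tidyr::pivot_longer(x$trace, c("train_loss", "test_loss"),
                      names_to = "partition", values_to = "loss") |>
    dplyr::mutate(partition = sub("_loss$", "", .data$partition))
}

#' @rdname tidy.cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble::tibble(
    best_step = x$best_step, best_test_loss = x$best_test_loss,
    stopped_early = x$stopped_early
  )
}

#' Summaries of a repeated-split evaluation
#'
#' @param x An `eval_result`.
#' @param ... Unused.
#' @return `tidy`: the per-split metrics tibble. `glance`: one row with
#'   means and standard deviations across splits.
#' @export
tidy.eval_result <- function(x, ...) x$metrics

#' @rdname tidy.eval_result
#' @export
glance.eval_result <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    n_splits = x$n_splits,
    mean_accuracy = mean(m$accuracy), sd_accuracy = stats::sd(m$accuracy),
    mean_precision = mean(m$precision, na.rm = TRUE),
    mean_recall = mean(m$recall, na.rm = TRUE),
    mean_auc = mean(m$auc, na.rm = TRUE), sd_auc = stats::sd(m$auc, na.rm = TRUE)
  )
}

#' Per-method summary of a benchmark run
#'
#' @param x A `benchmark_result` from [run_benchmark()].
#' @param ... Unused.
#' @return One row per method with mean/sd accuracy and AUC, plus the
#'   paired comparison of every method against `ae_cnn` ([paired
#'   t][paired_accuracy_ttest()] and Cohen's d).
#' @export
glance.benchmark_result <- function(x, ...) {
  ref <- dplyr::arrange(dplyr::filter(x, .data$method == "ae_cnn"), .data$split_id)
  x |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(.data$split_id, .by_group = TRUE) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$accuracy), sd_accuracy = stats::sd(.data$accuracy),
      mean_auc = mean(.data$auc),
      vs_ae_cnn = list(
        if (.data$method[1] == "ae_cnn") NULL
        else paired_accuracy_ttest(ref$accuracy, .data$accuracy)
      ),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("vs_ae_cnn", names_sep = "_")
}
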