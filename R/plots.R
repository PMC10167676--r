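#' Plot a training trace
#'
#' Train and held-out loss against optimizer step, log-scaled loss axis.
#'
#' @param object An `ae_fit` or `cnn_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ae_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$step, y = .data$loss,
                               colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "optimizer step", y = "reconstruction MSE",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.ae_fit
#' @export
autoplot.cnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$step, y = .data$loss,
                               colour = .data$partition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "optimizer step", y = "binary cross-entropy",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' ROC curves over repeated splits
#'
#' One translucent curve per split plus the chance diagonal.
#'
#' @param object An `eval_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eval_result <- function(object, ...) {
  ggplot2::ggplot(object$roc_curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               group = .data$split_id)) +
    ggplot2::geom_line(alpha = 0.25, colour = "steelblue") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Benchmark accuracies per method
#'
#' @param object A `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object (boxplot of per-split accuracies by method).
#' @export
autoplot.benchmark_result <- function(object, ...) {
  ord <- object |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(m = mean(.data$accuracy)) |>
    dplyr::arrange(dplyr::desc(.data$m))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$method, ord$method),
                               y = .data$accuracy)) +
    ggplot2::geom_boxplot(fill = "grey90") +
    ggplot2::labs(x = NULL, y = "test accuracy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Axial montage of a sensitivity or importance map
#'
#' @param map A `sensitivity_map`, or a plain 3-D array (e.g. a group
#'   importance map).
#' @param slices Integer z indices to show (default: 6 evenly spaced).
#' @return A ggplot object.
#' @export
plot_sensitivity_slices <- function(map, slices = NULL) {
  a <- if (inherits(map, "sensitivity_map")) map$normalized else map
  d <- dim(a)
  if (is.null(slices)) slices <- unique(round(seq(2, d[3] - 1, length.out = 6)))
  df <- purrr::map_dfr(slices, function(z) {
    tibble::tibble(
      x = rep(seq_len(d[1]), d[2]),
      y = rep(seq_len(d[2]), each = d[1]),
      value = as.vector(a[, , z]),
      slice = z
    )
  })
  lim <- max(abs(df$value), .Machine$double.eps)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "mean error") +
    ggplot2::theme_void()
}
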