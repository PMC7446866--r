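#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' ROC curve for validation risk scores
#'
#' Plots the empirical receiver operating characteristic of predicted
#' probabilities against known-case labels, with the chance diagonal for
#' reference.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Logical (or 0/1) outcome vector.
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(labels[ord]) / sum(labels)
  fpr <- cumsum(!labels[ord]) / sum(!labels)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("ROC curve (AUC = %.3f)", compute_auc(scores, labels))
    ) +
    ggplot2::theme_minimal()
}

#' Coefficient plot for a fitted homelessness model
#'
#' Dot-and-interval plot of the log-odds estimates (excluding the
#' intercept) with 95% Wald intervals.
#'
#' @param object A `homeless_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.homeless_model <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  td$term <- stats::reorder(td$term, td$estimate)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error
    )) +
    ggplot2::labs(x = "Log-odds of known homelessness", y = NULL) +
    ggplot2::theme_minimal()
}

#' Rate-ratio plot across risk-score schemes
#'
#' Point estimates with 95% confidence intervals on a log scale, one row
#' per scheme.
#'
#' @param object A `rate_comparison_set` from [compare_overdose_rates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rate_comparison_set <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rate_ratio, y = .data$scheme)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Fatal opioid overdose rate ratio (95% CI, log scale)",
      y = NULL
    ) +
    ggplot2::theme_minimal()
}
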