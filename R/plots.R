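#' Plot out-of-fold predictions against reference engagement
#'
#' @param object An `estimation_result`.
#' @param ... Unused.
#' @return A ggplot: predicted vs reference engagement, one point per
#'   (dyad, interval), with the identity line.
#' @export
autoplot.estimation_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$reference, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::coord_equal(xlim = c(0, 100), ylim = c(0, 100)) +
    ggplot2::labs(x = "Reference engagement (0-100)",
                  y = "Estimated engagement (0-100)",
                  title = sprintf("%s / %s: RMS %.1f, MA %.1f (medians)",
                                  object$mode, object$method,
                                  object$summary$rms_median,
                                  object$summary$ma_median)) +
    ggplot2::theme_minimal()
}

#' Compare per-dyad errors across methods
#'
#' @param result A `pipeline_result`.
#' @param metric `"rms_error"` or `"ma_error"`.
#' @return A ggplot: per-dyad error distributions (boxplots) per
#'   mode/method.
#' @export
plot_error_comparison <- function(result, metric = c("rms_error", "ma_error")) {
  metric <- match.arg(metric)
  df <- dplyr::bind_rows(lapply(names(result$results), function(k) {
    dplyr::mutate(result$results[[k]]$per_dyad, run = k)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data[[metric]])) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = sub("_", " ", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot averaged predictor importance
#'
#' @param importance Tibble from [predictor_importance()].
#' @param n Number of top features to show (default 15).
#' @return A ggplot bar chart of averaged, normalized importances.
#' @export
plot_importance <- function(importance, n = 15L) {
  df <- utils::head(importance, n)
  df$feature <- factor(df$feature, levels = rev(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Mean normalized importance", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
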