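#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a surface report
#'
#' Histogram of convexity scores of surface atoms, colored by label.
#'
#' @param object a surface report from [alpha_surface()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bindresp_surface <- function(object, ...) {
  df <- object[object$on_surface & !is.na(object$omega_prime), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$omega_prime,
                                   fill = .data$shape_label)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "convexity score cos(omega)/4", y = "surface atoms",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report as a confusion heatmap
#'
#' @param object a `bindresp_eval` from [evaluate()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.bindresp_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "pred", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted response", y = "true response",
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot a feature-group ablation table
#'
#' @param ablation_table tibble returned by [ablation()].
#' @return a ggplot with mean accuracy and +/- 1 sd error bars per group
#'   set.
#' @export
plot_ablation <- function(ablation_table) {
  ggplot2::ggplot(ablation_table,
                  ggplot2::aes(x = stats::reorder(.data$groups,
                                                  .data$mean_accuracy),
                               y = .data$mean_accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_accuracy - .data$sd_accuracy,
      ymax = .data$mean_accuracy + .data$sd_accuracy), width = 0.2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "mean outer-fold accuracy") +
    ggplot2::theme_minimal()
}

#' Plot the y-scrambling null distribution
#'
#' @param scramble result of [y_scramble()].
#' @param observed_accuracy optional unscrambled accuracy drawn as a
#'   vertical line.
#' @return a ggplot.
#' @export
plot_scramble <- function(scramble, observed_accuracy = NULL) {
  p <- ggplot2::ggplot(scramble$accuracies,
                       ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey60") +
    ggplot2::labs(x = "scrambled-label accuracy", y = "iterations") +
    ggplot2::theme_minimal()
  if (!is.null(observed_accuracy))
    p <- p + ggplot2::geom_vline(xintercept = observed_accuracy,
                                 color = "firebrick", linetype = 2)
  p
}
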