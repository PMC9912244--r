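# ggplot2 visualisations for the package's result objects.

#' Plot the training-loss history of a CRNN fit
#' @param object A trained `crnn_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crnn_model <- function(object, ...) {
  h <- tidy(object)
  h_long <- tidyr::pivot_longer(h, -"epoch", names_to = "series", values_to = "mse")
  ggplot2::ggplot(h_long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                       colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean squared error", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a position-by-nucleotide attribution summary
#' @param object An `attribution_summary` from [position_importance()].
#' @param ... Unused.
#' @return A ggplot (position on x, one line per nucleotide).
#' @export
autoplot.attribution_summary <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$position, y = .data$attribution,
                               colour = .data$nucleotide)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "spacer position (5' to 3')", y = "mean attribution") +
    ggplot2::theme_minimal()
}

#' Plot a control-choice benchmark
#' @param object A `control_benchmark` tibble.
#' @param ... Unused.
#' @return A ggplot of TPR and FPR against the FDR cutoff per control set.
#' @export
autoplot.control_benchmark <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("tpr", "fpr"),
                              names_to = "metric", values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$fdr_cutoff, y = .data$rate,
                                     colour = .data$control)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$metric) +
    ggplot2::labs(x = "FDR cutoff", y = "rate", colour = "control set") +
    ggplot2::theme_minimal()
}

#' Plot the sigmoid LFC-normalisation curve
#' @param params A [solve_sigmoid_params()] result.
#' @param xlim LFC range to draw.
#' @return A ggplot.
#' @export
plot_sigmoid <- function(params = solve_sigmoid_params(), xlim = c(-3, 2)) {
  x <- seq(xlim[1], xlim[2], length.out = 200)
  ggplot2::ggplot(tibble(lfc = x, target = lfc_to_target(x, params)),
                  ggplot2::aes(x = .data$lfc, y = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "log2 fold change", y = "normalised target score") +
    ggplot2::theme_minimal()
}
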