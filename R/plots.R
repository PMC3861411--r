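# ggplot2 visualizations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A `roc_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))) +
    ggplot2::theme_minimal()
}

#' Plot transfer error and transfer rate against the best-match threshold
#'
#' @param object A `transfer_eval` (see [pfm_transfer_eval()]). The dynamic
#'   row, if present, is drawn as horizontal reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.transfer_eval <- function(object, ...) {
  static <- object[object$mode == "static", ]
  dynamic <- object[object$mode == "dynamic", ]
  long <- tidyr::pivot_longer(static, c("transfer_error", "transfer_rate"),
                              names_to = "measure")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold,
                                          y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Best-match threshold", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(dynamic) == 1L) {
    ref <- tidyr::pivot_longer(dynamic, c("transfer_error", "transfer_rate"),
                               names_to = "measure")
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dotted", color = "firebrick")
  }
  p
}

#' Plot a PFM as a per-position probability chart
#'
#' @param x A [pfm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_pfm <- function(x, ...) {
  d <- tidy(x)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$probability,
                                  fill = .data$base)) +
    ggplot2::geom_col(position = "stack", width = 0.9) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::labs(title = x$id, x = "Position", y = "Probability",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
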