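# Plot helpers for result tables.

#' Plot conditional effects of a predictor on behavior probabilities
#'
#' @param ce tibble from [conditional_effects()] or [predict_multitask()].
#' @param x name of the predictor column to place on the x axis.
#' @return A ggplot with a median line and credible-interval ribbon, one
#'   facet per behavior category when present.
#' @export
plot_conditional_effects <- function(ce, x) {
  p <- ggplot2::ggplot(ce, ggplot2::aes(x = .data[[x]],
                                        y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "posterior probability")
  if ("category" %in% names(ce)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Plot a model-comparison table
#'
#' @param comparison tibble from [select_models()].
#' @return A ggplot of elpd differences with +/- 1 SE bars; retained models
#'   in black, excluded in grey.
#' @export
plot_comparison <- function(comparison) {
  comparison$model <- stats::reorder(comparison$model,
                                     comparison$elpd_diff)
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$elpd_diff, y = .data$model,
                               color = .data$retained)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$elpd_diff - .data$se_diff,
                   xmax = .data$elpd_diff + .data$se_diff),
      height = 0.2) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "black",
                                           `FALSE` = "grey60"),
                                guide = "none") +
    ggplot2::labs(x = "ELPD difference from top model", y = NULL)
}
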