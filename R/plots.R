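#' Net peritoneal calcium balance by PD modality
#'
#' Box-and-whisker display of the per-patient net peritoneal balance split
#' by modality, the standard way this cohort result is shown: APD (glucose
#' dialysates only) tends negative while modalities using an icodextrin
#' long dwell sit closer to, or above, zero.
#'
#' @param data Data frame with `modality` and a balance column.
#' @param balance_col Balance column to plot.
#' @return A ggplot object.
#' @export
plot_balance_by_modality <- function(data,
                                     balance_col = "peritoneal_balance_mmol_day") {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$modality, y = .data[[balance_col]], fill = .data$modality
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_boxplot(outlier.shape = 1, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Net peritoneal calcium balance (mmol/day)") +
    ggplot2::theme_minimal()
}

#' Forest plot of a backward logistic model
#'
#' Odds ratios with 95% Wald intervals for every retained term, on a log
#' scale with the null line at OR = 1.
#'
#' @param object A [backward_logistic()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_logistic <- function(object, ...) {
  td <- tidy(object)
  if (!nrow(td)) stop("No retained terms to plot.", call. = FALSE)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$odds_ratio, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high), height = 0.2
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Lollipop plot of a Spearman screen
#'
#' @param object Output of [spearman_screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_screen <- function(object, ...) {
  d <- dplyr::filter(object, !is.na(.data$rho))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$rho, y = stats::reorder(.data$variable, abs(.data$rho))
  )) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey60") +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$variable)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$p_value < 0.05), size = 2) +
    ggplot2::labs(x = "Spearman rho", y = NULL, colour = "p < 0.05") +
    ggplot2::theme_minimal()
}
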