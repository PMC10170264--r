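#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a smoothed calibration curve
#'
#' Smoothed observed-vs-predicted curve with the identity line and a rug of
#' the prediction distribution.
#'
#' @param object A `crp_calibration_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crp_calibration_curve <- function(object, ...) {
  risk <- attr(object, "risk")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_rug(data = tibble::tibble(predicted = risk),
                      ggplot2::aes(x = .data$predicted), inherit.aes = FALSE,
                      alpha = 0.05, sides = "b") +
    ggplot2::labs(x = "Predicted 10-year risk", y = "Observed (pseudovalue smooth)") +
    ggplot2::theme_minimal()
}

#' Plot decision curves
#'
#' Net benefit against threshold probability for the model, treat-all and
#' treat-none strategies.
#'
#' @param object A `crp_decision_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crp_decision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$threshold,
                                       y = .data$net_benefit,
                                       colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(-0.02, NA)) +
    ggplot2::labs(x = "Threshold probability", y = "Net benefit",
                  colour = NULL,
                  subtitle = if (isTRUE(attr(object, "competing")))
                    "Accounting for competing risks" else
                    "Not accounting for competing risks") +
    ggplot2::theme_minimal()
}

#' Forest plot of region-level IECV metrics
#'
#' Region estimates with 95% CIs, the HKSJ pooled diamond row and the 95%
#' prediction interval, for one metric across models.
#'
#' @param result A `crp_iecv` object.
#' @param metric Metric to display (e.g. `"harrell_c"`, `"ipcw_c"`,
#'   `"slope"`, `"citl"`).
#' @return A ggplot object.
#' @export
plot_forest <- function(result, metric = "slope") {
  stopifnot(inherits(result, "crp_iecv"))
  cl <- result$cluster_metrics |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::mutate(label = paste("region", .data$region),
                  ci_low = .data$value - 1.96 * .data$se,
                  ci_high = .data$value + 1.96 * .data$se)
  po <- result$meta |>
    dplyr::filter(.data$metric == !!metric) |>
    dplyr::mutate(label = "pooled (95% CI)", value = .data$estimate)
  ggplot2::ggplot(cl, ggplot2::aes(y = .data$label, x = .data$value)) +
    ggplot2::geom_point(shape = 18, size = 2) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_point(data = po, shape = 23, size = 3, fill = "black") +
    ggplot2::geom_errorbarh(data = po,
                            ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_errorbarh(data = po,
                            ggplot2::aes(xmin = .data$pi_low,
                                         xmax = .data$pi_high),
                            height = 0, linetype = 3) +
    ggplot2::facet_wrap(~ model) +
    ggplot2::labs(x = metric, y = NULL) +
    ggplot2::theme_minimal()
}
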