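
# ggplot2 views of the result objects.

#' Plot a depth sweep
#'
#' Mean simulated rate per hidden-layer depth with its percentile CI ribbon;
#' dashed lines mark the observed physician baselines.
#'
#' @param object An `ot_depth_sweep` tibble from [depth_sweep()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ot_depth_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$simulated)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$baseline),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Hidden layers", y = "Simulated rate (%)",
                  title = "Policy capacity sweep (twin-simulated outcomes)")
}

#' Plot one-step or start-to-finish accuracies
#'
#' @param object An `ot_accuracy_report` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ot_accuracy_report <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      feature = factor(.data$feature,
                                       levels = rev(unique(.data$feature))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy, y = .data$feature)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lower, xmax = .data$upper)) +
    ggplot2::labs(x = "Accuracy (%)", y = NULL,
                  title = "Treatment-simulator prediction accuracy (95% CI)")
}

#' Plot prescription-rate changes
#'
#' @param object An `ot_prescription_delta` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ot_prescription_delta <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$decision, y = .data$delta)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_prescribed),
                       vjust = -0.4, size = 3) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = "Decision point",
                  y = "Prescription-rate change vs physicians (points)",
                  title = "Model vs physician prescription rates")
}
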