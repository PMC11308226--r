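# ggplot2 displays for calibration curves, pooled results (forest plots),
# and per-cluster cross-validation estimates.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_abline
#'   geom_errorbar geom_errorbarh geom_vline labs theme_minimal coord_cartesian
#' @export
ggplot2::autoplot

#' Plot a calibration curve
#'
#' Quantile-bin points (mean predicted vs observed fraction) with the smooth
#' curve and the ideal diagonal.
#'
#' @param object A [calibration_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.calibration_curve <- function(object, ...) {
  ggplot(object$bins, aes(x = .data$p_mean, y = .data$obs_frac)) +
    geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    geom_line(data = object$smooth, aes(x = .data$p, y = .data$p_observed),
              colour = "#2166ac") +
    geom_point(aes(size = .data$n), alpha = 0.8) +
    coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    labs(x = "Predicted probability", y = "Observed fraction",
         size = "Patients") +
    theme_minimal()
}

#' Forest plot of a pooled result
#'
#' @param object A [meta_pool()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.meta_result <- function(object, ...) {
  fd <- forest_data(object)
  fd$label <- factor(fd$label, levels = rev(fd$label))
  ggplot(fd, aes(x = .data$estimate, y = .data$label,
                 colour = .data$type)) +
    geom_vline(xintercept = object$pooled, linetype = "dotted",
               colour = "grey50") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2) +
    geom_point(aes(shape = .data$type), size = 2.5) +
    ggplot2::scale_colour_manual(values = c(cluster = "grey25",
                                            pooled = "#b2182b"),
                                 guide = "none") +
    ggplot2::scale_shape_manual(values = c(cluster = 16, pooled = 18),
                                guide = "none") +
    labs(
      x = "Estimate", y = NULL,
      subtitle = sprintf("Pooled %.2f (%.2f to %.2f); I² = %.0f%%",
                         object$pooled, object$ci_low, object$ci_high,
                         object$i2)
    ) +
    theme_minimal()
}

#' Per-cluster performance dot plot for a cross-validation result
#'
#' @param object An `iecv_result` from [loco_cv()].
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot faceted by metric.
#' @export
autoplot.iecv_result <- function(object, metrics = metric_names(), ...) {
  est <- filter(object$estimates, .data$metric %in% metrics)
  ggplot(est, aes(x = .data$value, y = .data$cluster_id)) +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0.2, colour = "grey40") +
    geom_point(size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_x") +
    labs(x = "Estimate (95% CI)", y = NULL) +
    theme_minimal()
}
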