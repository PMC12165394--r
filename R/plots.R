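#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_vline
#'   geom_tile geom_errorbarh labs theme_minimal facet_wrap
#'   scale_fill_gradient2
#' @export
ggplot2::autoplot

#' Plot a trial recording's COM trajectory
#'
#' Forward excursion and COM height against time; for TUG trials, detected
#' event times can be overlaid.
#'
#' @param object A [trial_recording()].
#' @param events Optional `tug_events` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trial_recording <- function(object, events = NULL, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$data, "t", "com_x", "com_z"),
    c("com_x", "com_z"), names_to = "series", values_to = "value"
  )
  p <- ggplot(df, aes(x = .data$t, y = .data$value)) +
    geom_line() +
    facet_wrap(~ .data$series, ncol = 1, scales = "free_y") +
    labs(x = "time (s)", y = "position (m)",
         title = sprintf("%s (%s)", object$trial_id, object$condition)) +
    theme_minimal()
  if (!is.null(events)) {
    p <- p + geom_vline(data = events$times,
                        aes(xintercept = .data$time), linetype = "dashed",
                        colour = "grey40")
  }
  p
}

#' Plot detected gait events over the relative heel trajectory
#'
#' @param object A `gait_events` tibble.
#' @param trial The matching [trial_recording()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gait_events <- function(object, trial = NULL, ...) {
  p <- ggplot(object, aes(x = .data$time, y = .data$side,
                          shape = .data$event, colour = .data$event)) +
    geom_point(size = 3) +
    labs(x = "time (s)", y = "side", title = "Detected gait events") +
    theme_minimal()
  p
}

#' Correlation heat map of the battery
#'
#' Mirrors the usual presentation of the cognitive-by-gait correlation
#' battery: predictors on one axis, dependents on the other, fill by r,
#' significant cells outlined.
#'
#' @param report A `stat_report` or the correlation tibble itself.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(report) {
  cor_tab <- if (inherits(report, "stat_report")) report$correlations else report
  ggplot(cor_tab, aes(x = .data$predictor, y = .data$dependent,
                      fill = .data$r)) +
    geom_tile(colour = "white") +
    scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                         limits = c(-1, 1)) +
    geom_point(data = dplyr::filter(cor_tab, .data$significant),
               aes(x = .data$predictor, y = .data$dependent),
               inherit.aes = FALSE, shape = 8, size = 1.5) +
    labs(x = NULL, y = NULL, fill = "r",
         title = "Cognitive-gait correlation battery") +
    theme_minimal()
}

#' Forest plot of correlation estimates with confidence intervals
#'
#' @param report A `stat_report` or correlation tibble.
#' @param predictor Optional predictor to restrict to.
#' @return A ggplot object.
#' @export
plot_correlation_forest <- function(report, predictor = NULL) {
  cor_tab <- if (inherits(report, "stat_report")) report$correlations else report
  if (!is.null(predictor)) {
    cor_tab <- dplyr::filter(cor_tab, .data$predictor == !!predictor)
  }
  ggplot(cor_tab, aes(x = .data$r, y = .data$dependent,
                      colour = .data$method)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_lower, xmax = .data$ci_upper),
                   height = 0.2) +
    geom_vline(xintercept = 0, linetype = "dotted") +
    facet_wrap(~ .data$predictor) +
    labs(x = "correlation (95% CI)", y = NULL) +
    theme_minimal()
}
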