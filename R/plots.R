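#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a census forecast fan
#'
#' @param object a [forecast_census()] result.
#' @param ... unused.
#' @return a ggplot: point forecast with the percentile interval by horizon.
#' @export
autoplot.census_forecast <- function(object, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(x = .data$origin + .data$horizon)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$point), colour = "steelblue") +
    ggplot2::annotate("point", x = object$origin, y = object$census, shape = 4) +
    ggplot2::labs(x = "day", y = "census",
                  title = paste0("Census forecast from day ", object$origin)) +
    ggplot2::theme_minimal()
}

#' Plot observed versus forecast census from a backtest
#'
#' @param object a [run_backtest()] report.
#' @param horizons subset of horizons to show (default: all).
#' @param ... unused.
#' @return a ggplot faceted by horizon: observed census, point forecast, and
#'   the percentile prediction interval over the test window.
#' @export
autoplot.backtest_report <- function(object, horizons = NULL, ...) {
  d <- object$daily
  if (!is.null(horizons)) d <- d[d$horizon %in% horizons, , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$point, colour = "forecast")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed, colour = "observed")) +
    ggplot2::facet_wrap(~horizon, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(NULL, values = c(forecast = "steelblue",
                                                  observed = "black")) +
    ggplot2::labs(x = "day", y = "census") +
    ggplot2::theme_minimal()
}

#' Accuracy-by-horizon plot
#'
#' Mean absolute prediction error (with its 95% CI) by forecast horizon,
#' for the ensemble model and, when present, the census-only benchmark.
#'
#' @param report a [run_backtest()] report.
#' @return a ggplot.
#' @export
plot_mape <- function(report) {
  d <- glance(report)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$horizon, y = .data$mape,
                                  colour = .data$model)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mape_lo,
                                          ymax = .data$mape_hi),
                             position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.2)) +
    ggplot2::labs(x = "forecast horizon (days)",
                  y = "mean absolute prediction error (patients)") +
    ggplot2::theme_minimal()
}

#' Interval-width boxplots
#'
#' Distribution of 95% prediction-interval widths by horizon and model.
#'
#' @param report a [run_backtest()] report.
#' @return a ggplot.
#' @export
plot_interval_widths <- function(report) {
  d <- tidy(report)
  d$width <- d$hi - d$lo
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$horizon), y = .data$width,
                                  fill = .data$model)) +
    ggplot2::geom_boxplot(alpha = 0.6) +
    ggplot2::labs(x = "forecast horizon (days)",
                  y = "95% prediction-interval width (patients)") +
    ggplot2::theme_minimal()
}

#' Plot a frequency scan
#'
#' @param object an [estimate_frequency()] result.
#' @param ... unused.
#' @return a ggplot of the periodogram ordinates over the candidate
#'   frequencies, with the selected frequency highlighted.
#' @export
autoplot.frequency_scan <- function(object, ...) {
  d <- object$periodogram
  ggplot2::ggplot(d, ggplot2::aes(x = .data$frequency, y = .data$ordinate)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_col(data = d[d$frequency == object$omega_hat, , drop = FALSE],
                      fill = "steelblue") +
    ggplot2::labs(x = "frequency (cycles per series)", y = "periodogram") +
    ggplot2::theme_minimal()
}
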