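#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an EVI time series
#'
#' @param data EVI series table.
#' @param threshold Horizontal reference line (the dry-period
#'   threshold); `NULL` suppresses it.
#' @return A ggplot object.
#' @export
plot_evi_series <- function(data, threshold = 0.3) {
  data <- check_evi_series(data, complete = FALSE)
  p <- ggplot2::ggplot(data,
                       ggplot2::aes(x = .data$date, y = .data$evi,
                                    colour = .data$site)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "EVI", colour = "site") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot the average annual EVI profile
#'
#' Cross-year mean with a plus/minus one SD ribbon per site.
#'
#' @param profile Output of [annual_profile()] (an EVI series table is
#'   also accepted and profiled first).
#' @param threshold Horizontal reference line; `NULL` suppresses it.
#' @return A ggplot object.
#' @export
plot_annual_profile <- function(profile, threshold = 0.3) {
  if (!"mean_evi" %in% names(profile)) profile <- annual_profile(profile)
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = .data$doy, y = .data$mean_evi,
                                    colour = .data$site,
                                    fill = .data$site)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_evi - .data$sd_evi,
      ymax = .data$mean_evi + .data$sd_evi), alpha = 0.2,
      colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of year", y = "EVI") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold,
                                 colour = "red", linetype = 2)
  }
  p
}

#' Plot an interannual metric trend
#'
#' Yearly values of one phenology metric with its least-squares trend
#' line.
#'
#' @param metrics Table from [extract_all_metrics()].
#' @param metric Metric column name (e.g. `"sdo"`).
#' @return A ggplot object.
#' @export
plot_metric_trend <- function(metrics, metric) {
  stopifnot(metric %in% names(metrics))
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$year,
                               y = .data[[metric]],
                               colour = .data$site)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Year", y = toupper(metric)) +
    ggplot2::theme_minimal()
}

pred_obs_plot <- function(predictions, title) {
  ggplot2::ggplot(predictions,
                  ggplot2::aes(x = .data$observed,
                               y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed EVI", y = "Modelled EVI",
                  title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.evi_mlr <- function(object, ...) {
  pred_obs_plot(object$predictions,
                paste("MLR:", paste(object$selected, collapse = " + ")))
}

#' @export
autoplot.evi_rf <- function(object, ...) {
  pred_obs_plot(object$predictions,
                sprintf("Random forest (test months, R^2 = %.2f)",
                        object$r2_test))
}
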