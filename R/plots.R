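# ggplot2 views of the main result types.

#' Plot the monthly engagement trend
#'
#' Line plot of the monthly mean response rate (or the percent of users
#' with zero responses) by engagement stratum, one line per overall level.
#'
#' @param trend Output of [trend_metrics()].
#' @param metric `"mean_rate"` or `"pct_zero"`.
#' @return A ggplot object.
#' @export
plot_engagement_trend <- function(trend, metric = c("mean_rate", "pct_zero")) {
  metric <- match.arg(metric)
  lab <- switch(metric,
                mean_rate = "mean monthly response rate",
                pct_zero = "share of users with zero responses")
  ggplot2::ggplot(trend, ggplot2::aes(
    x = .data$month, y = .data[[metric]],
    colour = .data$level, group = .data$level
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(trend$month))) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "month of follow-up", y = lab,
                  colour = "overall level") +
    ggplot2::theme_minimal()
}

#' @rdname plot_engagement_trend
#' @param object An `engagement_trend` tibble.
#' @param ... Passed to [plot_engagement_trend()].
#' @method autoplot engagement_trend
#' @export
autoplot.engagement_trend <- function(object, ...) {
  plot_engagement_trend(object, ...)
}

#' Plot retention by engagement group
#'
#' @param x A [retention_by_level()] result.
#' @return A ggplot object.
#' @export
plot_retention <- function(x) {
  stopifnot(inherits(x, "retention_result"))
  d <- x$rates
  d$category <- d[[x$group]]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$retention)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = x$group, y = "retention rate at 6 months") +
    ggplot2::theme_minimal()
}

#' @rdname plot_retention
#' @param object A `retention_result`.
#' @param ... Unused.
#' @method autoplot retention_result
#' @export
autoplot.retention_result <- function(object, ...) {
  plot_retention(object)
}

#' Plot mean response rate by rating bin
#'
#' @param fig3 Output of [response_by_rating_figure_data()].
#' @return A ggplot object.
#' @export
plot_response_by_rating <- function(fig3) {
  ggplot2::ggplot(fig3, ggplot2::aes(x = .data$rating_bin,
                                     y = .data$mean_response_rate)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "level of mean influence rating",
                  y = "mean response rate") +
    ggplot2::theme_minimal()
}
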