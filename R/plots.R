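# ggplot2 displays for the main result types.

#' Plot cycle-by-cycle activity trajectories
#'
#' One panel per length category, cycle index on the x axis, the chosen
#' metric for both populations on the y axis.
#'
#' @param trajectories long trajectory table ([recovered_trajectories()] or
#'   [tidy_trajectories()]).
#' @param metric `"spikes_per_cycle"`, `"participation"` or
#'   `"spikes_per_burst"`.
#' @param lengths length categories to show.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, metric = "spikes_per_cycle",
                              lengths = c(6, 14)) {
  tr <- as_long_trajectories(trajectories) %>%
    filter(.data$length_k %in% lengths)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$cycle_index,
                                   y = .data[[metric]],
                                   colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~length_k, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = c(TC = "black", nRT = "magenta")) +
    ggplot2::labs(x = "cycle index", y = metric, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter display of a trajectory correlation
#'
#' One dot per spindle-length category, with the fitted line and the
#' correlation in the title.
#'
#' @param object a `"spindle_cor"` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.spindle_cor <- function(object, ...) {
  d <- object$pairs
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(
      title = sprintf("%s (%s %s): r = %.2f, p = %.3g",
                      object$analysis, object$population, object$metric,
                      object$r, object$p),
      x = if (object$analysis == "first_cycle_vs_duration")
        "spindle length (cycles)" else "first cycle",
      y = if (object$analysis == "first_cycle_vs_duration")
        "first-cycle value" else "last cycle") +
    ggplot2::theme_minimal()
}

#' Plot an evoked-probability curve
#'
#' @param curve output of [probability_curve()].
#' @return A ggplot object.
#' @export
plot_probability_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$level, y = .data$p_evoked)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_lo,
                                          ymax = .data$ci_hi)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "stimulus level", y = "evoked-spindle probability") +
    ggplot2::theme_minimal()
}

#' Plot a smoothed MUA trace with detected events
#'
#' @param trace a [smooth_mua()] trace.
#' @param events optional event tibble; detected windows are shaded.
#' @param xlim optional time range (seconds).
#' @return A ggplot object.
#' @export
plot_mua <- function(trace, events = NULL, xlim = NULL) {
  d <- trace
  if (!is.null(xlim)) d <- d[d$time_s >= xlim[1] & d$time_s <= xlim[2], ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$rate)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "MUA rate (spikes/s)") +
    ggplot2::theme_minimal()
  if (!is.null(events) && nrow(events) > 0) {
    ev <- events
    if (!is.null(xlim)) {
      ev <- ev[ev$offset_s >= xlim[1] & ev$onset_s <= xlim[2], ]
    }
    p <- p + ggplot2::geom_rect(
      data = ev, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$onset_s, xmax = .data$offset_s,
                   ymin = -Inf, ymax = Inf),
      fill = "steelblue", alpha = 0.15)
  }
  p
}
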