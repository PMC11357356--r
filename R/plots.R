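# ggplot2 figures for the standard result types.

behavior_palette <- c(
  roll = "#d62728", crawl = "#1f77b4", turn = "#2ca02c", hunch = "#9467bd",
  stop = "#7f7f7f", backup = "#ff7f0e", unknown = "#e0e0e0")

#' Ethogram raster plot
#'
#' One row per larva, colored by per-frame behavior; stimulation windows
#' shaded.
#'
#' @param ethograms Ethogram tibble from [classify_frames()].
#' @param trial Optional [trial_design()] to shade stimulation windows.
#' @return A ggplot object.
#' @export
plot_ethogram <- function(ethograms, trial = NULL) {
  p <- ggplot2::ggplot(ethograms,
         ggplot2::aes(x = .data$t, y = .data$larva_id, fill = .data$label)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = behavior_palette, name = "behavior") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(trial)) p <- p + stim_shading(trial)
  p
}

stim_shading <- function(trial) {
  w <- dplyr::bind_rows(lapply(trial$stim_windows, function(x)
    tibble::tibble(xmin = x[1], xmax = x[2])))
  ggplot2::geom_rect(data = w, ggplot2::aes(xmin = .data$xmin,
      xmax = .data$xmax, ymin = -Inf, ymax = Inf),
    inherit.aes = FALSE, fill = "red", alpha = 0.08)
}

#' Behavior probability time series plot
#'
#' Per-frame behavior probability with its confidence band (shaded), the
#' standard population readout figure.
#'
#' @param prob_ts Output of [probability_timeseries()].
#' @param trial Optional [trial_design()] for stimulation shading.
#' @return A ggplot object.
#' @export
plot_probability_timeseries <- function(prob_ts, trial = NULL) {
  p <- ggplot2::ggplot(prob_ts, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$proportion)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (s)", y = "probability") +
    ggplot2::theme_minimal()
  if (!is.null(trial)) p <- p + stim_shading(trial)
  p
}

#' Cumulative bout-duration plot
#'
#' Empirical CDFs of bout durations, optionally split by group.
#'
#' @param durations Numeric vector, or a tibble with `duration_s` and an
#'   optional `group` column.
#' @return A ggplot object.
#' @export
plot_cumulative_durations <- function(durations) {
  if (is.numeric(durations))
    durations <- tibble::tibble(duration_s = durations)
  aes <- if ("group" %in% names(durations)) {
    ggplot2::aes(x = .data$duration_s, color = .data$group)
  } else ggplot2::aes(x = .data$duration_s)
  ggplot2::ggplot(durations, aes) +
    ggplot2::stat_ecdf() +
    ggplot2::labs(x = "bout duration (s)", y = "cumulative fraction") +
    ggplot2::theme_minimal()
}

#' Plot a trial-averaged dF/F response
#'
#' @param object A `dff_series` from [compute_dff()].
#' @param ... Unused.
#' @return A ggplot object with single-trial traces (grey) and the
#'   trial average (black).
#' @method autoplot dff_series
#' @export
autoplot.dff_series <- function(object, ...) {
  ggplot2::ggplot(object$trials,
      ggplot2::aes(x = .data$t_rel_s, y = .data$dff,
                   group = .data$trial)) +
    ggplot2::geom_line(color = "grey70") +
    ggplot2::geom_line(data = object$mean,
                       ggplot2::aes(group = NULL), color = "black") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "red") +
    ggplot2::labs(x = "time from stimulation onset (s)",
                  y = expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
}

#' Plot a dose-response fit
#'
#' @param object A `dose_response_fit`.
#' @param ... Unused.
#' @return A ggplot object of peak dF/F against irradiance with the fitted
#'   line.
#' @method autoplot dose_response_fit
#' @export
autoplot.dose_response_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
      ggplot2::aes(x = .data$irradiance, y = .data$peak_dff)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "red") +
    ggplot2::labs(x = expression("irradiance (" * mu * "W/mm"^2 * ")"),
                  y = expression("peak " * Delta * F / F[0])) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
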