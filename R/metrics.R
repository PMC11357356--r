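# Per-larva and population escape-sequence metrics.

#' Binned behavior probability in a window
#'
#' Proportion of larvae that performed a behavior at least once within a
#' window — by default the first 5 s after stimulation onset, the standard
#' population-level readout — with a two-sided 95% Wilson score interval.
#' For rolls, "performed" requires a bout of at least `min_roll_bout_s`.
#'
#' @param bouts Population bout tibble ([segment_bouts()] output). Larvae not
#'   tracked through the full stimulation window should be excluded upstream
#'   (see [filter_tracks()] and [run_pipeline()]).
#' @param trial A [trial_design()]; its first stimulation window anchors the
#'   default bin.
#' @param behavior Behavior to score (default `"roll"`).
#' @param window Optional `c(start_s, end_s)` overriding the default
#'   `[onset, onset + bin_s)` window.
#' @param bin_s Width of the default window, seconds.
#' @param min_roll_bout_s Minimum qualifying roll-bout duration, seconds.
#' @param conf_level Confidence level of the interval.
#' @param n_larvae Optional total number of tracked larvae; defaults to the
#'   number of distinct `larva_id`s in `bouts` (supply it when some tracked
#'   larvae produced no bouts at all).
#' @return One-row tibble: `behavior`, `k`, `n`, `proportion`, `conf_low`,
#'   `conf_high`.
#' @examples
#' b <- tibble::tibble(larva_id = c("a", "b"), behavior = c("roll", "crawl"),
#'                     start_s = c(46, 46), end_s = c(48, 50))
#' binned_probability(b, trial_design())
#' @export
binned_probability <- function(bouts, trial, behavior = "roll", window = NULL,
                               bin_s = 5, min_roll_bout_s = 0.2,
                               conf_level = 0.95, n_larvae = NULL) {
  if (is.null(window)) {
    if (!length(trial$stim_windows)) abort("trial has no stimulation window")
    on <- trial$stim_windows[[1]][1]
    window <- c(on, on + bin_s)
  }
  ids <- unique(bouts$larva_id)
  n <- n_larvae %||% length(ids)
  if (n == 0) abort("no larvae to score")
  hit <- vapply(ids, function(id) {
    bb <- bouts[bouts$larva_id == id & bouts$behavior == behavior, , drop = FALSE]
    if (!nrow(bb)) return(FALSE)
    ok <- bb$start_s < window[2] & bb$end_s > window[1]
    if (behavior == "roll")
      ok <- ok & (bb$end_s - bb$start_s) >= min_roll_bout_s - 1e-9
    any(ok)
  }, logical(1))
  k <- sum(hit)
  ci <- wilson_ci(k, n, conf_level)
  tibble::tibble(behavior = behavior, k = k, n = n, proportion = k / n,
                 conf_low = ci[1], conf_high = ci[2])
}

#' Per-frame behavior probability time series
#'
#' For every frame, the fraction of tracked larvae whose ethogram label is
#' the given behavior, with a pointwise Wilson confidence band.
#'
#' @param ethograms Ethogram tibble from [classify_frames()].
#' @param behavior Behavior to score.
#' @param conf_level Confidence level of the band.
#' @return Tibble `t`, `k`, `n`, `proportion`, `conf_low`, `conf_high`.
#' @export
probability_timeseries <- function(ethograms, behavior = "roll",
                                   conf_level = 0.95) {
  out <- ethograms %>%
    group_by(t = .data$t) %>%
    summarise(k = sum(.data$label == .env$behavior), n = dplyr::n(),
              .groups = "drop")
  if (nrow(out) == 0) abort("no frames to score")
  ci <- t(mapply(wilson_ci, out$k, out$n, MoreArgs = list(level = conf_level)))
  out %>% mutate(proportion = .data$k / .data$n,
                 conf_low = ci[, 1], conf_high = ci[, 2])
}

#' Per-larva escape metrics for one stimulation window
#'
#' From each larva's bouts, extracts the escape-sequence parameters measured
#' from stimulation onset: roller status (full-window and first-5-s
#' variants), total rolling time within the window, onset and offset of the
#' first roll bout, onset of the first crawl bout after that roll, and the
#' roll-offset-to-crawl-onset gap. A larva that rolled but never crawled
#' again before the window closed gets the window length (30 s for the
#' standard design) as its crawl-onset value; non-rollers get missing values
#' for all roll-derived fields and are excluded from latency samples.
#'
#' @param bouts Population bout tibble.
#' @param trial A [trial_design()].
#' @param window_index Which stimulation window to analyze (default 1).
#' @param min_roll_bout_s Minimum qualifying roll-bout duration, seconds.
#' @param bin_s Width of the early-response roller window, seconds.
#' @return Tibble with one row per larva: `larva_id`, `is_roller`,
#'   `is_roller_5s`, `total_roll_s`, `first_roll_onset_s`,
#'   `first_roll_offset_s`, `first_crawl_after_roll_s`, `roll_to_crawl_gap_s`
#'   (all latencies in seconds from window onset).
#' @examples
#' b <- tibble::tibble(larva_id = "a", behavior = c("roll", "crawl"),
#'                     start_s = c(47, 50), end_s = c(50, 64))
#' escape_metrics(b, trial_design())
#' @export
escape_metrics <- function(bouts, trial, window_index = 1,
                           min_roll_bout_s = 0.2, bin_s = 5) {
  if (window_index > length(trial$stim_windows)) abort("no such stimulation window")
  w <- trial$stim_windows[[window_index]]
  wlen <- w[2] - w[1]
  one <- function(bb) {
    qual <- bb$behavior == "roll" &
      (bb$end_s - bb$start_s) >= min_roll_bout_s - 1e-9 &
      bb$start_s < w[2] & bb$end_s > w[1]
    rolls <- bb[qual, , drop = FALSE]
    roller <- nrow(rolls) > 0
    roller5 <- any(qual & bb$start_s < w[1] + bin_s & bb$end_s > w[1])
    total_roll <- sum(pmin(rolls$end_s, w[2]) - pmax(rolls$start_s, w[1]))
    if (roller) {
      fr <- rolls[which.min(rolls$start_s), ]
      onset <- max(fr$start_s, w[1]) - w[1]
      offset <- min(fr$end_s, w[2]) - w[1]
      crawls <- bb[bb$behavior == "crawl" & bb$end_s > fr$end_s &
                     bb$start_s < w[2], , drop = FALSE]
      crawls <- crawls[pmax(crawls$start_s, fr$end_s) < w[2], , drop = FALSE]
      crawl_on <- if (nrow(crawls)) {
        max(min(pmax(crawls$start_s, fr$end_s)), w[1]) - w[1]
      } else wlen
      gap <- crawl_on - offset
    } else {
      onset <- offset <- crawl_on <- gap <- NA_real_
      total_roll <- if (roller) total_roll else 0
    }
    tibble::tibble(is_roller = roller, is_roller_5s = roller5,
                   total_roll_s = total_roll,
                   first_roll_onset_s = onset, first_roll_offset_s = offset,
                   first_crawl_after_roll_s = crawl_on,
                   roll_to_crawl_gap_s = gap)
  }
  bouts %>%
    group_by(.data$larva_id) %>%
    dplyr::group_modify(~ one(.x)) %>%
    ungroup()
}

#' Empirical cumulative distribution of bout durations
#'
#' Sorted durations with cumulative fractions — the "cumulative plot" used to
#' compare bout-duration distributions between groups.
#'
#' @param durations Numeric vector of bout durations, seconds.
#' @return Tibble `duration_s`, `cumulative_fraction` (non-decreasing,
#'   ending at 1).
#' @examples
#' cumulative_duration_distribution(c(1, 2, 3))
#' @export
cumulative_duration_distribution <- function(durations) {
  durations <- durations[!is.na(durations)]
  if (!length(durations)) abort("no durations supplied")
  d <- sort(durations)
  tibble::tibble(duration_s = d,
                 cumulative_fraction = seq_along(d) / length(d))
}

#' Population speed time series
#'
#' Per-frame mean and standard error of centroid speed across larvae,
#' optionally restricted to frames carrying a given ethogram label (e.g.
#' crawl frames only, to compare crawl speed in and out of stimulation).
#'
#' @param features Feature tibble from [compute_features()].
#' @param ethograms Optional ethogram tibble; required when `behavior` is set.
#' @param behavior Optional behavior mask.
#' @return Tibble `t`, `n`, `mean_speed`, `se_speed`.
#' @export
speed_timeseries <- function(features, ethograms = NULL, behavior = NULL) {
  df <- features
  if (!is.null(behavior)) {
    if (is.null(ethograms)) abort("ethograms needed to mask by behavior")
    df <- df %>%
      left_join(ethograms, by = c("larva_id", "t")) %>%
      filter(.data$label == .env$behavior)
  }
  df %>%
    filter(!is.na(.data$speed)) %>%
    group_by(t = .data$t) %>%
    summarise(n = dplyr::n(), mean_speed = mean(.data$speed),
              se_speed = ifelse(dplyr::n() > 1,
                                sd(.data$speed) / sqrt(dplyr::n()), 0),
              .groups = "drop")
}
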