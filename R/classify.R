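# Rule-based per-frame behavior classification and bout segmentation.
#
# Transparent, threshold-based rules stand in for trained classifiers: a
# frame is a roll when the body is C-shaped (high three-chord curvature) and
# the larva moves sideways (high crabspeed/speed) — the operational rolling
# definition — with fixed priority roll > hunch > stop > turn > backup >
# crawl resolving frames that satisfy several rules.

#' Classifier thresholds
#'
#' Thresholds of the rule-based classifier. None of these are dictated by the
#' assay itself except `min_roll_bout_s`: a roll event must last at least
#' 0.2 s (one full rotation at the fastest observable rolling rate) to count,
#' and a larva is a "roller" if it has at least one such event in the window.
#'
#' @param roll_curvature_min Minimum body curvature for a roll frame, degrees.
#' @param roll_crab_ratio_min Minimum crabspeed/speed ratio for a roll frame.
#' @param crawl_speed_min Minimum speed for crawl/backup, mm/s.
#' @param turn_head_angle_min Minimum head angle for a turn frame, degrees.
#' @param hunch_length_drop Fractional body-length drop (within a 0.5-s
#'   lookback) that marks a hunch.
#' @param stop_speed_max Maximum speed of a stop frame, mm/s.
#' @param min_roll_bout_s Minimum duration of a counted roll bout, seconds
#'   (inclusive: a bout of exactly this duration counts).
#' @param merge_gap_s Same-behavior bouts separated by at most this gap are
#'   merged, seconds.
#' @return An object of class `classifier_thresholds`.
#' @export
classifier_thresholds <- function(roll_curvature_min = 45,
                                  roll_crab_ratio_min = 0.5,
                                  crawl_speed_min = 0.3,
                                  turn_head_angle_min = 30,
                                  hunch_length_drop = 0.15,
                                  stop_speed_max = 0.1,
                                  min_roll_bout_s = 0.2,
                                  merge_gap_s = 0.1) {
  vals <- list(roll_curvature_min = roll_curvature_min,
               roll_crab_ratio_min = roll_crab_ratio_min,
               crawl_speed_min = crawl_speed_min,
               turn_head_angle_min = turn_head_angle_min,
               hunch_length_drop = hunch_length_drop,
               stop_speed_max = stop_speed_max,
               min_roll_bout_s = min_roll_bout_s,
               merge_gap_s = merge_gap_s)
  bad <- names(vals)[!vapply(vals, function(v) is.numeric(v) && is.finite(v) && v >= 0, logical(1))]
  if (length(bad)) abort(paste("invalid thresholds:", paste(bad, collapse = ", ")))
  if (min_roll_bout_s <= 0) abort("min_roll_bout_s must be positive")
  structure(vals, class = "classifier_thresholds")
}

# Largest length within the preceding `w` frames (inclusive), per larva block.
rolling_max_prev <- function(x, w) {
  n <- length(x)
  out <- x
  for (k in seq_len(min(w, n - 1))) out <- pmax(out, dplyr::lag(x, k, default = -Inf))
  out
}

#' Classify frames into an ethogram
#'
#' Applies the rule set per frame, in priority order: **roll** if curvature
#' and the crabspeed/speed ratio exceed their thresholds and the larva is
#' moving; else **hunch** if body length has dropped by at least
#' `hunch_length_drop` relative to its maximum over the preceding 0.5 s;
#' else **stop** if speed is at or below `stop_speed_max`; else **turn** if
#' the head angle exceeds its threshold while forward speed is below
#' `crawl_speed_min`; else **backup** if moving with negative bias; else
#' **crawl** if moving; else **unknown**. Frames with missing features are
#' labeled `unknown`.
#'
#' @param features Feature tibble from [compute_features()].
#' @param thresholds A [classifier_thresholds()].
#' @return Tibble `larva_id`, `t`, `label` (the ethogram), with the rule set
#'   recorded in the `"classifier_meta"` attribute.
#' @examples
#' pop <- simulate_population(sim_config(n_larvae = 2, seed = 1))
#' etho <- classify_frames(compute_features(pop$tracks))
#' table(etho$label)
#' @export
classify_frames <- function(features, thresholds = classifier_thresholds()) {
  thr <- thresholds
  req <- c("larva_id", "t", "speed", "crabspeed", "curvature", "head_angle",
           "length", "bias", "forward_speed")
  if (!all(req %in% names(features)))
    abort("features must come from compute_features()")
  out <- features %>%
    group_by(.data$larva_id) %>%
    mutate(.dt = median(diff(.data$t)),
           .lmax = rolling_max_prev(.data$length, pmax(1L, round(0.5 / first(.data$.dt)))),
           .ldrop = 1 - .data$length / .data$.lmax) %>%
    ungroup() %>%
    mutate(
      .crab_ratio = ifelse(.data$speed > 0, .data$crabspeed / .data$speed, 0),
      label = dplyr::case_when(
        is.na(.data$speed) | is.na(.data$curvature) ~ "unknown",
        .data$curvature >= thr$roll_curvature_min &
          .data$.crab_ratio >= thr$roll_crab_ratio_min &
          .data$speed > thr$stop_speed_max ~ "roll",
        .data$.ldrop >= thr$hunch_length_drop ~ "hunch",
        .data$speed <= thr$stop_speed_max ~ "stop",
        .data$head_angle >= thr$turn_head_angle_min &
          .data$forward_speed < thr$crawl_speed_min ~ "turn",
        .data$bias < 0 & .data$speed >= thr$crawl_speed_min ~ "backup",
        .data$speed >= thr$crawl_speed_min ~ "crawl",
        TRUE ~ "unknown")) %>%
    select(all_of(c("larva_id", "t", "label")))
  attr(out, "classifier_meta") <- list(
    rules = "threshold rules; priority roll > hunch > stop > turn > backup > crawl",
    thresholds = unclass(thr))
  out
}

#' Segment an ethogram into behavior bouts
#'
#' Run-length encodes per-frame labels into maximal bouts (half-open
#' `[start_s, end_s)`; duration = frames x frame interval), merges
#' same-behavior bouts separated by interruptions of at most `merge_gap_s`,
#' and removes roll bouts shorter than `min_roll_bout_s` (inclusive
#' threshold) by relabeling them to the preceding bout's behavior (the
#' following bout's at track start, `unknown` if alone).
#'
#' @param ethogram Tibble from [classify_frames()] (or any tibble with
#'   `larva_id`, `t`, `label`).
#' @param thresholds A [classifier_thresholds()].
#' @return Tibble `larva_id`, `behavior`, `start_s`, `end_s`, `duration_s`,
#'   sorted by larva and onset.
#' @examples
#' etho <- tibble::tibble(larva_id = "a", t = seq(0, 1.1, 0.1),
#'                        label = rep(c("roll", "crawl"), each = 6))
#' segment_bouts(etho)
#' @export
segment_bouts <- function(ethogram, thresholds = classifier_thresholds()) {
  thr <- thresholds
  one <- function(df) {
    df <- df[order(df$t), ]
    dt <- if (nrow(df) > 1) median(diff(df$t)) else 1
    r <- rle(df$label)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    b <- tibble::tibble(behavior = r$values,
                        start_s = df$t[starts],
                        end_s = df$t[ends] + dt)
    b <- merge_bouts(b, thr$merge_gap_s)
    # drop sub-threshold roll bouts into a flank, then re-merge
    repeat {
      short <- which(b$behavior == "roll" &
                       (b$end_s - b$start_s) < thr$min_roll_bout_s - 1e-9)
      if (!length(short)) break
      i <- short[1]
      b$behavior[i] <- if (i > 1) b$behavior[i - 1]
        else if (nrow(b) > 1) b$behavior[i + 1] else "unknown"
      b <- merge_bouts(b, thr$merge_gap_s)
    }
    b
  }
  out <- ethogram %>%
    group_by(.data$larva_id) %>%
    dplyr::group_modify(~ one(.x)) %>%
    ungroup() %>%
    mutate(duration_s = .data$end_s - .data$start_s) %>%
    arrange(.data$larva_id, .data$start_s)
  out
}

# Merge same-behavior bouts separated by gaps <= merge_gap_s, absorbing the
# interruption; then collapse adjacent identical behaviors.
merge_bouts <- function(b, merge_gap_s) {
  if (nrow(b) < 2) return(b)
  repeat {
    merged <- FALSE
    i <- 1
    while (i <= nrow(b) - 2) {
      gap <- b$end_s[i + 1] - b$start_s[i + 1]
      if (b$behavior[i] == b$behavior[i + 2] &&
          b$behavior[i] != b$behavior[i + 1] &&
          gap <= merge_gap_s + 1e-9) {
        b$end_s[i] <- b$end_s[i + 2]
        b <- b[-c(i + 1, i + 2), ]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  # collapse adjacent identical labels
  if (nrow(b) > 1) {
    same <- c(FALSE, b$behavior[-1] == b$behavior[-nrow(b)] &
                abs(b$start_s[-1] - b$end_s[-nrow(b)]) < 1e-9)
    grp <- cumsum(!same)
    b <- tibble::tibble(
      behavior = b$behavior[!same],
      start_s = as.numeric(tapply(b$start_s, grp, min)),
      end_s = as.numeric(tapply(b$end_s, grp, max)))
  }
  b
}

#' Roller labeling
#'
#' A larva is a *roller* in a window if at least one roll bout of duration
#' `>= min_roll_bout_s` overlaps the window (boundary inclusive: a single
#' bout of exactly the minimum duration counts).
#'
#' @param bouts Bout tibble for one larva ([segment_bouts()] output).
#' @param window `c(start_s, end_s)` in trial time.
#' @param min_roll_bout_s Minimum qualifying bout duration, seconds.
#' @return Logical flag.
#' @examples
#' b <- tibble::tibble(behavior = "roll", start_s = 46, end_s = 47)
#' label_roller(b, c(45, 75))
#' @export
label_roller <- function(bouts, window, min_roll_bout_s = 0.2) {
  stopifnot(length(window) == 2, window[2] > window[1])
  rolls <- bouts[bouts$behavior == "roll", , drop = FALSE]
  if (!nrow(rolls)) return(FALSE)
  overlaps <- rolls$start_s < window[2] & rolls$end_s > window[1]
  any(overlaps & (rolls$end_s - rolls$start_s) >= min_roll_bout_s - 1e-9)
}
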