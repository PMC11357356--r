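# Stimulation-locked dF/F analysis of ROI fluorescence traces.

#' Downsample a calcium trace by bin averaging
#'
#' Averages fluorescence into non-overlapping time bins at the target rate
#' (e.g. 30 fps acquisition to the 6 fps analysis rate). Stimulation onsets
#' and irradiance are preserved.
#'
#' @param trace A [calcium_trace()].
#' @param target_hz Target rate, fps (must not exceed the native rate).
#' @return A [calcium_trace()] at `target_hz`, timestamps at bin centers.
#' @export
downsample_trace <- function(trace, target_hz = 6) {
  if (!inherits(trace, "calcium_trace")) abort("trace must be a calcium_trace")
  if (target_hz > trace$native_rate_hz + 1e-9)
    abort("target rate exceeds native rate")
  bin <- floor(trace$data$t_s * target_hz + 1e-9)
  out <- trace$data %>%
    mutate(.bin = bin) %>%
    group_by(.data$.bin) %>%
    summarise(f = mean(.data$f), .groups = "drop") %>%
    mutate(t_s = (.data$.bin + 0.5) / target_hz)
  calcium_trace(out$t_s, out$f, trace$stim_onsets,
                irradiance = trace$irradiance, native_rate_hz = target_hz)
}

#' Stimulation-locked dF/F
#'
#' For each stimulation onset: the baseline `F0` is the mean of the 10 frames
#' immediately preceding the onset (1.67 s at the 6 fps analysis rate); `F`
#' is averaged in consecutive 5-frame bins spanning from 5 s before the onset
#' to 15 s after it; and `dF/F = (F - F0)/F0` per bin. The per-ROI response
#' is the across-trial average of the per-trial dF/F traces (three trials in
#' the standard design). Trials with `F0 <= 0` or insufficient pre/post
#' context are dropped with a warning, never imputed.
#'
#' @param trace A [calcium_trace()], normally already at the analysis rate
#'   (see [downsample_trace()]).
#' @param f0_frames Frames averaged for the baseline.
#' @param bin_frames Frames per dF/F bin.
#' @param pre_s,post_s Analysis span around each onset, seconds.
#' @return An object of class `dff_series`: list with `trials` (tibble
#'   `trial`, `bin`, `t_rel_s`, `dff`; `t_rel_s` is the bin-center time
#'   relative to onset), `mean` (trial-averaged tibble `bin`, `t_rel_s`,
#'   `dff`), `f0` (per-trial baselines), `irradiance`.
#' @examples
#' sim <- simulate_gcamp(gcamp_config(irradiances = 0.5, noise_sd = 0))
#' dff <- compute_dff(downsample_trace(sim$traces[["0.5"]]))
#' peak_dff(dff)
#' @export
compute_dff <- function(trace, f0_frames = 10, bin_frames = 5,
                        pre_s = 5, post_s = 15) {
  if (!inherits(trace, "calcium_trace")) abort("trace must be a calcium_trace")
  t <- trace$data$t_s; f <- trace$data$f
  rate <- trace$native_rate_hz
  n_bins <- floor((pre_s + post_s) * rate / bin_frames)
  trials <- list(); f0s <- numeric(0)
  for (k in seq_along(trace$stim_onsets)) {
    on <- trace$stim_onsets[k]
    i_on <- which(t >= on - 1e-9)[1]
    i_start <- which(t >= on - pre_s - 1e-9)[1]
    if (is.na(i_on) || i_on - f0_frames < 1) {
      warn(sprintf("trial %d dropped: fewer than %d pre-onset frames", k, f0_frames))
      next
    }
    if (is.na(i_start) || i_start + n_bins * bin_frames - 1 > length(t)) {
      warn(sprintf("trial %d dropped: insufficient post-onset context", k))
      next
    }
    f0 <- mean(f[(i_on - f0_frames):(i_on - 1)])
    if (f0 <= 0) {
      warn(sprintf("trial %d dropped: non-positive baseline F0", k))
      next
    }
    idx <- i_start + seq_len(n_bins * bin_frames) - 1
    bin <- rep(seq_len(n_bins), each = bin_frames)
    Fb <- tapply(f[idx], bin, mean)
    tb <- tapply(t[idx], bin, mean) - on
    trials[[length(trials) + 1]] <- tibble::tibble(
      trial = k, bin = seq_len(n_bins), t_rel_s = as.numeric(tb),
      dff = as.numeric((Fb - f0) / f0))
    f0s <- c(f0s, f0)
  }
  if (!length(trials)) abort("no usable trials")
  trials <- dplyr::bind_rows(trials)
  avg <- trials %>%
    group_by(.data$bin) %>%
    summarise(t_rel_s = mean(.data$t_rel_s), dff = mean(.data$dff),
              .groups = "drop")
  structure(list(trials = trials, mean = avg, f0 = f0s,
                 irradiance = trace$irradiance,
                 rate_hz = rate, bin_frames = bin_frames),
            class = "dff_series")
}

#' @export
print.dff_series <- function(x, ...) {
  cat("<dff_series> ", max(x$trials$trial), " trial(s), ",
      nrow(x$mean), " bins of ", x$bin_frames, " frames at ",
      round(x$rate_hz, 2), " fps\n", sep = "")
  invisible(x)
}

#' Peak dF/F of a stimulation-locked response
#'
#' Maximum of the trial-averaged dF/F over bins whose centers lie within
#' `[onset, onset + post_s]`, and the bin-center time at which it occurs.
#'
#' @param dff A `dff_series` from [compute_dff()].
#' @param post_s Search window after onset, seconds.
#' @return One-row tibble: `peak_dff`, `peak_time_s`, `irradiance`.
#' @export
peak_dff <- function(dff, post_s = 15) {
  if (!inherits(dff, "dff_series")) abort("dff must be a dff_series")
  win <- dff$mean %>% filter(.data$t_rel_s >= 0, .data$t_rel_s <= post_s)
  if (!nrow(win)) abort("no bins in the peak-search window")
  i <- which.max(win$dff)
  tibble::tibble(peak_dff = win$dff[i], peak_time_s = win$t_rel_s[i],
                 irradiance = dff$irradiance)
}

#' Dose-response fit of peak dF/F against irradiance
#'
#' Least-squares line of peak dF/F versus stimulation irradiance, the
#' standard summary of a linear dose-dependent response.
#'
#' @param peaks Tibble with columns `irradiance` and `peak_dff` (>= 3
#'   distinct irradiances).
#' @return An object of class `dose_response_fit`; see [tidy()] and
#'   [glance()] methods, and `$slope`, `$intercept`, `$r_squared`.
#' @examples
#' peaks <- tibble::tibble(irradiance = c(0.1, 0.5, 1.4),
#'                         peak_dff = c(0.1, 0.5, 1.4))
#' glance(dose_response(peaks))
#' @export
dose_response <- function(peaks) {
  if (!all(c("irradiance", "peak_dff") %in% names(peaks)))
    abort("peaks must have irradiance and peak_dff columns")
  peaks <- peaks[complete.cases(peaks[c("irradiance", "peak_dff")]), ]
  if (length(unique(peaks$irradiance)) < 3)
    abort("need >= 3 distinct irradiances")
  fit <- lm(peak_dff ~ irradiance, data = peaks)
  ss_res <- sum(resid(fit)^2)
  ss_tot <- sum((peaks$peak_dff - mean(peaks$peak_dff))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(fit = fit, data = tibble::as_tibble(peaks),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r_squared = r2),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("<dose_response_fit> slope ", signif(x$slope, 4), " dF/F per uW/mm^2, ",
      "intercept ", signif(x$intercept, 4), ", R^2 ", signif(x$r_squared, 4),
      "\n", sep = "")
  invisible(x)
}

#' Tidy a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return Coefficient tibble (`term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`).
#' @method tidy dose_response_fit
#' @export
tidy.dose_response_fit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' One-row summary of a dose-response fit
#'
#' @param x A `dose_response_fit`.
#' @param ... Unused.
#' @return Tibble `slope`, `intercept`, `r.squared`, `nobs`.
#' @method glance dose_response_fit
#' @export
glance.dose_response_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 r.squared = x$r_squared, nobs = nrow(x$data))
}
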