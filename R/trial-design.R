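#' Optogenetic trial design
#'
#' Describes the timing of an optogenetic behavior trial: a pre-stimulus
#' acclimation period followed by one or more stimulation windows. The default
#' reproduces the standard escape assay: larvae acclimate for 45 s, then
#' receive two 30-s LED stimulations separated by a 30-s rest, tracked at
#' 10 frames/s (165 s total).
#'
#' @param pre_stim_s Seconds of pre-stimulus acclimation.
#' @param stim_windows List of `c(onset_s, offset_s)` pairs, in seconds from
#'   trial start. Windows must be disjoint, ordered, and inside the trial.
#' @param frame_rate_hz Tracking frame rate (frames per second).
#' @param total_s Total trial duration in seconds. Defaults to the end of the
#'   last stimulation window plus a 30-s post period when windows exist.
#' @param irradiance Stimulation power density in uW/mm^2 (informational).
#'
#' @return An object of class `trial_design`.
#' @examples
#' trial_design()
#' trial_design(pre_stim_s = 5, stim_windows = list(c(5, 35)), total_s = 65)
#' @export
trial_design <- function(pre_stim_s = 45,
                         stim_windows = list(c(45, 75), c(105, 135)),
                         frame_rate_hz = 10,
                         total_s = NULL,
                         irradiance = NA_real_) {
  stopifnot(is.numeric(pre_stim_s), pre_stim_s >= 0, frame_rate_hz > 0)
  stim_windows <- lapply(stim_windows, as.numeric)
  if (length(stim_windows)) {
    ok <- vapply(stim_windows, function(w) length(w) == 2 && w[2] > w[1], logical(1))
    if (!all(ok)) abort("each stimulation window must be c(onset_s, offset_s) with offset > onset")
    onsets <- vapply(stim_windows, `[`, numeric(1), 1)
    offsets <- vapply(stim_windows, `[`, numeric(1), 2)
    if (is.unsorted(onsets, strictly = TRUE) || any(onsets[-1] < offsets[-length(offsets)]))
      abort("stimulation windows must be ordered and disjoint")
    if (any(onsets < 0)) abort("stimulation windows must start at or after 0")
  }
  if (is.null(total_s)) {
    total_s <- if (length(stim_windows)) max(vapply(stim_windows, `[`, numeric(1), 2)) + 30 else pre_stim_s
  }
  if (length(stim_windows) && max(vapply(stim_windows, `[`, numeric(1), 2)) > total_s)
    abort("stimulation windows must end within total_s")
  structure(
    list(pre_stim_s = pre_stim_s, stim_windows = stim_windows,
         frame_rate_hz = frame_rate_hz, total_s = total_s,
         irradiance = irradiance),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat("<trial_design> ", x$total_s, " s at ", x$frame_rate_hz, " fps; pre-stimulus ",
      x$pre_stim_s, " s\n", sep = "")
  for (w in x$stim_windows)
    cat("  stimulation ", w[1], "-", w[2], " s\n", sep = "")
  invisible(x)
}

#' Frame times of a trial
#'
#' @param trial A [trial_design()].
#' @return Numeric vector of frame start times (seconds); frame i covers the
#'   half-open interval `[t_i, t_i + 1/frame_rate_hz)`.
#' @export
trial_times <- function(trial) {
  n <- round(trial$total_s * trial$frame_rate_hz)
  seq(0, by = 1 / trial$frame_rate_hz, length.out = n)
}

#' Is a time point inside a stimulation window?
#'
#' Uses the half-open convention `[onset, offset)`.
#'
#' @param t Numeric vector of times (seconds).
#' @param trial A [trial_design()].
#' @return Logical vector.
#' @export
in_stimulation <- function(t, trial) {
  out <- rep(FALSE, length(t))
  for (w in trial$stim_windows) out <- out | (t >= w[1] & t < w[2])
  out
}
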