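# Synthetic GCaMP fluorescence traces with stored ground truth.

# Normalized double-exponential response kernel: zero before the onset lag
# t0, rises with tau_r, decays with tau_d, peak value 1 at peak_delay_s.
gcamp_kernel <- function(t, rise_tau_s, decay_tau_s, peak_delay_s) {
  tstar <- log(decay_tau_s / rise_tau_s) * rise_tau_s * decay_tau_s /
    (decay_tau_s - rise_tau_s)
  if (peak_delay_s < tstar)
    abort(sprintf(
      "peak_delay_s (%.3g) cannot precede the kernel's natural peak (%.3g s)",
      peak_delay_s, tstar))
  t0 <- peak_delay_s - tstar
  s <- pmax(t - t0, 0)
  cnorm <- exp(-tstar / decay_tau_s) - exp(-tstar / rise_tau_s)
  (exp(-s / decay_tau_s) - exp(-s / rise_tau_s)) / cnorm
}

#' A calcium trace object
#'
#' Bundles an ROI-mean fluorescence time series with its stimulation
#' metadata.
#'
#' @param t Frame times, seconds (strictly increasing).
#' @param f ROI-mean fluorescence, arbitrary units (>= 0).
#' @param stim_onsets Stimulation onset times, seconds, inside `[t0, t_end]`.
#' @param irradiance Stimulation power density, uW/mm^2.
#' @param native_rate_hz Acquisition frame rate, fps.
#' @return An object of class `calcium_trace`.
#' @export
calcium_trace <- function(t, f, stim_onsets, irradiance = NA_real_,
                          native_rate_hz = NULL) {
  if (length(t) != length(f)) abort("t and f must have equal length")
  if (any(diff(t) <= 0)) abort("t must be strictly increasing")
  if (any(f < 0)) abort("fluorescence must be non-negative")
  if (any(stim_onsets < t[1] | stim_onsets > t[length(t)]))
    abort("every stimulation onset must lie within the trace")
  structure(
    list(data = tibble::tibble(t_s = t, f = f),
         stim_onsets = as.numeric(stim_onsets), irradiance = irradiance,
         native_rate_hz = native_rate_hz %||% (1 / median(diff(t)))),
    class = "calcium_trace")
}

#' @export
print.calcium_trace <- function(x, ...) {
  cat("<calcium_trace> ", nrow(x$data), " frames at ",
      round(x$native_rate_hz, 2), " fps; ", length(x$stim_onsets),
      " stimulation(s); irradiance ", x$irradiance, " uW/mm^2\n", sep = "")
  invisible(x)
}

#' Simulate GCaMP traces across an irradiance series
#'
#' For each irradiance, generates a fluorescence trace containing
#' `n_trials` stimulations: baseline fluorescence modulated by a
#' double-exponential response kernel whose peak dF/F is
#' `amplitude_slope x irradiance` (exact linear dose dependence by
#' construction) and peaks `peak_delay_s` after onset, plus additive Gaussian
#' noise. The generating truth (per-irradiance peak dF/F and peak time) is
#' returned alongside, so parameter-recovery tests need no re-derivation.
#'
#' @param config A [gcamp_config()].
#' @return A list: `traces` (named list of [calcium_trace()], one per
#'   irradiance), `truth` (tibble `irradiance`, `peak_dff`, `peak_time_s`),
#'   `config`.
#' @examples
#' sim <- simulate_gcamp(gcamp_config(irradiances = c(0.1, 0.5), noise_sd = 0))
#' sim$truth
#' @export
simulate_gcamp <- function(config) {
  if (!inherits(config, "gcamp_config")) abort("config must be a gcamp_config")
  cfg <- config
  dt <- 1 / cfg$frame_rate_hz
  total_s <- cfg$lead_in_s + cfg$n_trials * cfg$inter_trial_s
  t <- seq(0, total_s, by = dt)
  onsets <- cfg$lead_in_s + (seq_len(cfg$n_trials) - 1) * cfg$inter_trial_s
  traces <- list()
  withr::with_seed(cfg$seed, {
    for (irr in cfg$irradiances) {
      resp <- rowSums(vapply(onsets, function(on)
        gcamp_kernel(t - on, cfg$rise_tau_s, cfg$decay_tau_s, cfg$peak_delay_s),
        numeric(length(t))))
      f <- cfg$baseline_f * (1 + cfg$amplitude_slope * irr * resp)
      if (cfg$noise_sd > 0) f <- f + rnorm(length(f), 0, cfg$noise_sd)
      f <- pmax(f, 0)
      traces[[as.character(irr)]] <-
        calcium_trace(t, f, onsets, irradiance = irr,
                      native_rate_hz = cfg$frame_rate_hz)
    }
  })
  truth <- tibble::tibble(irradiance = cfg$irradiances,
                          peak_dff = cfg$amplitude_slope * cfg$irradiances,
                          peak_time_s = cfg$peak_delay_s)
  list(traces = traces, truth = truth, config = cfg)
}
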