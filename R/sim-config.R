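#' Configuration for the synthetic larva simulator
#'
#' Parameters of the ground-truthed larva simulator. Behavior sequences are
#' drawn from a stimulus-gated semi-Markov chain (explicit bout-duration
#' distributions, not per-frame transitions) and rendered as 2-D spine-point
#' chains at the trial frame rate. Defaults are calibrated to the escape
#' assay this package targets: each larva rolls during a stimulation window
#' with probability `p_roll`; roll bout durations follow a gamma distribution
#' (mean 0.8 s by default, the short-bout regime; 1.4 s is the disinhibited
#' regime) truncated below at `min_roll_bout_s`; crawling during stimulation
#' runs at `stim_crawl_multiplier` (~1.5) times the baseline crawl speed.
#'
#' @param n_larvae Number of larvae to simulate.
#' @param trial A [trial_design()].
#' @param p_roll Probability that a larva rolls in a given stimulation window.
#' @param roll_bout_mean_s Mean of the (untruncated) gamma roll-bout duration, s.
#' @param roll_bout_shape Gamma shape of the roll-bout duration.
#' @param baseline_crawl_speed Baseline crawl speed, mm/s.
#' @param stim_crawl_multiplier Crawl-speed multiplier inside stimulation
#'   windows (dimensionless).
#' @param inter_bout_crawl If `TRUE`, successive roll bouts are separated by a
#'   short crawl gap; if `FALSE` a roller produces a single bout per window.
#' @param body_length_mm Resting body length, mm.
#' @param n_spine_points Spine points per frame (tail to head); >= 5.
#' @param noise_sd_mm SD of isotropic Gaussian positional noise added to every
#'   spine point, mm.
#' @param seed Master seed; each larva gets its own stream derived from it, so
#'   populations are stable under reordering.
#' @param p_rebout Probability that a roller starts another roll bout after an
#'   inter-bout crawl gap (geometric bout count).
#' @param roll_latency_range_s Range (s) of the uniform latency from
#'   stimulation onset to the first roll bout.
#' @param inter_bout_gap_mean_s Mean (s) of the gamma crawl gap between roll
#'   bouts (shape 2).
#' @param roll_speed Translational speed during rolling, mm/s.
#' @param roll_omega_deg_s Rotation rate of the C-shaped body during rolling,
#'   degrees/s.
#' @param baseline_dwell_mean_s Mean (s) of the gamma dwell in baseline crawl
#'   before an interruption episode (shape 3).
#' @param min_roll_bout_s Minimum roll bout duration in the ground truth, s.
#'   Bout draws are resampled above this floor.
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_larvae = 5, seed = 1)
#' @export
sim_config <- function(n_larvae = 100,
                       trial = trial_design(),
                       p_roll = 0.6,
                       roll_bout_mean_s = 0.8,
                       roll_bout_shape = 3,
                       baseline_crawl_speed = 0.7,
                       stim_crawl_multiplier = 1.5,
                       inter_bout_crawl = TRUE,
                       body_length_mm = 4,
                       n_spine_points = 11,
                       noise_sd_mm = 0.02,
                       seed = 1L,
                       p_rebout = 0.5,
                       roll_latency_range_s = c(0.3, 1.5),
                       inter_bout_gap_mean_s = 1,
                       roll_speed = 1.2,
                       roll_omega_deg_s = 360,
                       baseline_dwell_mean_s = 5,
                       min_roll_bout_s = 0.2) {
  num_ok <- function(x) is.numeric(x) && all(is.finite(x))
  if (!num_ok(n_larvae) || n_larvae < 0) abort("n_larvae must be a non-negative number")
  if (!inherits(trial, "trial_design")) abort("trial must be a trial_design")
  if (!num_ok(p_roll) || p_roll < 0 || p_roll > 1) abort("p_roll must be in [0, 1]")
  for (nm in c("roll_bout_mean_s", "roll_bout_shape", "baseline_crawl_speed",
               "stim_crawl_multiplier", "body_length_mm", "roll_speed",
               "inter_bout_gap_mean_s", "baseline_dwell_mean_s", "min_roll_bout_s")) {
    v <- get(nm)
    if (!num_ok(v) || v <= 0) abort(paste0(nm, " must be a positive finite number"))
  }
  if (!num_ok(noise_sd_mm) || noise_sd_mm < 0) abort("noise_sd_mm must be >= 0")
  if (!num_ok(n_spine_points) || n_spine_points < 5) abort("n_spine_points must be >= 5")
  if (!num_ok(p_rebout) || p_rebout < 0 || p_rebout > 1) abort("p_rebout must be in [0, 1]")
  if (!num_ok(roll_latency_range_s) || length(roll_latency_range_s) != 2 ||
      any(roll_latency_range_s < 0) || diff(roll_latency_range_s) < 0)
    abort("roll_latency_range_s must be an increasing non-negative pair")
  structure(
    list(n_larvae = as.integer(n_larvae), trial = trial, p_roll = p_roll,
         roll_bout_mean_s = roll_bout_mean_s, roll_bout_shape = roll_bout_shape,
         baseline_crawl_speed = baseline_crawl_speed,
         stim_crawl_multiplier = stim_crawl_multiplier,
         inter_bout_crawl = isTRUE(inter_bout_crawl),
         body_length_mm = body_length_mm,
         n_spine_points = as.integer(n_spine_points),
         noise_sd_mm = noise_sd_mm, seed = as.integer(seed),
         p_rebout = p_rebout, roll_latency_range_s = roll_latency_range_s,
         inter_bout_gap_mean_s = inter_bout_gap_mean_s,
         roll_speed = roll_speed, roll_omega_deg_s = roll_omega_deg_s,
         baseline_dwell_mean_s = baseline_dwell_mean_s,
         min_roll_bout_s = min_roll_bout_s),
    class = "sim_config"
  )
}

#' Configuration for the synthetic GCaMP trace generator
#'
#' Emulates stimulation-locked somatic/axonal GCaMP responses: per irradiance,
#' a fluorescence trace containing `n_trials` stimulations separated by
#' `inter_trial_s`, with a double-exponential response kernel whose peak
#' amplitude is linear in irradiance (`amplitude_slope` dF/F per uW/mm^2) and
#' whose peak occurs `peak_delay_s` after stimulus onset. Ground truth (true
#' peak dF/F and peak time per irradiance) is stored with the trace so
#' parameter-recovery tests need no re-derivation.
#'
#' @param frame_rate_hz Acquisition frame rate, fps.
#' @param n_trials Stimulations per trace.
#' @param inter_trial_s Interval between stimulation onsets, s.
#' @param stim_dur_s Stimulus train duration, s (informational).
#' @param irradiances Power densities, uW/mm^2.
#' @param amplitude_slope True peak dF/F per unit irradiance.
#' @param rise_tau_s,decay_tau_s Kernel time constants, s (`decay > rise`).
#' @param peak_delay_s Time from onset to kernel peak, s.
#' @param baseline_f Baseline fluorescence, arbitrary units (> 0).
#' @param noise_sd SD of additive Gaussian noise, fluorescence units.
#' @param lead_in_s Recording time before the first onset, s (>= 5 s so the
#'   dF/F pre-window exists).
#' @param seed Seed for the noise stream.
#'
#' @return An object of class `gcamp_config`.
#' @export
gcamp_config <- function(frame_rate_hz = 30,
                         n_trials = 3,
                         inter_trial_s = 30,
                         stim_dur_s = 1,
                         irradiances = c(0.04, 0.1, 0.3, 0.5, 1.4),
                         amplitude_slope = 1.0,
                         rise_tau_s = 0.8,
                         decay_tau_s = 6,
                         peak_delay_s = 3,
                         baseline_f = 100,
                         noise_sd = 1,
                         lead_in_s = 10,
                         seed = 1L) {
  stopifnot(frame_rate_hz > 0, n_trials >= 1, inter_trial_s > 0,
            baseline_f > 0, noise_sd >= 0, lead_in_s >= 5,
            all(irradiances >= 0), rise_tau_s > 0)
  if (decay_tau_s <= rise_tau_s)
    abort("decay_tau_s must exceed rise_tau_s (kernel is ill-posed otherwise)")
  structure(
    list(frame_rate_hz = frame_rate_hz, n_trials = as.integer(n_trials),
         inter_trial_s = inter_trial_s, stim_dur_s = stim_dur_s,
         irradiances = as.numeric(irradiances),
         amplitude_slope = amplitude_slope, rise_tau_s = rise_tau_s,
         decay_tau_s = decay_tau_s, peak_delay_s = peak_delay_s,
         baseline_f = baseline_f, noise_sd = noise_sd,
         lead_in_s = lead_in_s, seed = as.integer(seed)),
    class = "gcamp_config"
  )
}

# Derived per-larva seed: stable under population reordering and bounded
# below 2^31 so it is a valid R integer.
larva_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) * 48271 + i * 16807) %% 2147483647)
}
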