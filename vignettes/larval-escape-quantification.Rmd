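---
title: "Quantifying larval escape behavior: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval escape behavior: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaquant)
library(dplyr)
```

This vignette is the package's own account of its science: the models it
implements, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the decisions taken where the design was
genuinely open.

## The escape sequence and the trial design

Nociceptive stimulation drives a *Drosophila* larva through a stereotyped
sequence: escape rolling — the body held in a C-shape rotating about its
long axis, which translates the animal perpendicular to its body axis —
followed by fast crawling at roughly 1.5× the baseline crawl speed. The
standard optogenetic assay tracks a plate of larvae at 10 frames/s through
a 45-s acclimation period and two 30-s stimulation windows separated by a
30-s rest; `trial_design()` encodes exactly this timing and all analyses
use the half-open convention `[onset, offset)` in seconds.

The pipeline starts from spine tracks (per-frame chains of 11 2-D points,
tail first, in mm), not video: contour extraction and head/tail
disambiguation are upstream tracker concerns and out of scope here.

## Per-frame kinematics

`compute_features()` reimplements the Choreography-style parameter set.
Since the original software's smoothing kernel and some definitions are not
published, this module's definitions are declared substitutes and recorded
in the output metadata:

* **centroid** — mean of the spine points (no contours are used);
* **speed** — magnitude of the centroid velocity, after smoothing the
  centroid with a centered moving average (default window 0.3 s, i.e. 3
  frames at 10 fps) and differencing centrally (one-sided at the track
  endpoints). The short window suppresses tracker jitter without masking
  sub-second bouts;
* **crabspeed** — the component of centroid velocity perpendicular to the
  tail→head chord. The projection inequality crabspeed ≤ speed holds by
  construction and is tested;
* **curvature** — the angle between the tail→midpoint and midpoint→head
  chords, in degrees. A straight body scores 0°, a semicircular C-shape
  exactly 90° (the geometry: each half-chord of a semicircle subtends a
  quarter turn). The three-chord angle was chosen over an integrated
  tangent angle because it is stable with only 11 spine points and maps
  directly onto the C-shape notion the roll definition uses;
* **head angle** — the angle between the head-quarter segment and the body
  axis;
* **bias** — (time moving forward − time moving backward) / (time moving)
  in a 1-s sliding window, where forward means positive projection of
  velocity on the body axis and frames slower than the stop threshold
  (0.1 mm/s) are excluded. Frames with no moving neighbors score 0.

Frames with a degenerate spine (all points coincident) are flagged and
their motion features set to missing; the classifier labels them `unknown`.

`filter_tracks()` applies the standard rejection rule: a track must be
followed for at least 5 s *and* move at least one body length. "One body
length" is the track's *median* spine arclength, robust to hunches, and
"moved" is the maximum excursion of the smoothed centroid from its starting
point — robust both to closed-loop paths (a larva circling back has still
moved) and to positional noise, which inflates a summed path length even
for a stationary animal.

## The rule-based ethogram

The original analyses used a trained roll classifier and a referenced
unsupervised classifier for the other behaviors; neither's decision
boundaries are published. `classify_frames()` substitutes transparent
threshold rules, applied per frame in fixed priority order (roll > hunch >
stop > turn > backup > crawl), with every threshold configurable through
`classifier_thresholds()`:

| parameter | default | units | role |
|---|---|---|---|
| `roll_curvature_min` | 45 | deg | C-shape gate for rolling |
| `roll_crab_ratio_min` | 0.5 | — | sideways-motion gate (crabspeed/speed) |
| `stop_speed_max` | 0.1 | mm/s | stationary threshold |
| `crawl_speed_min` | 0.3 | mm/s | locomotion threshold |
| `turn_head_angle_min` | 30 | deg | head-bend gate |
| `hunch_length_drop` | 0.15 | — | fractional length drop within 0.5 s |
| `min_roll_bout_s` | 0.2 | s | minimum counted roll bout |
| `merge_gap_s` | 0.1 | s | bout-merge gap |

Only `min_roll_bout_s` is dictated by the assay itself: a roll event must
last at least 0.2 s — one full rotation at the fastest observable rolling
rate — to count, and a *roller* is a larva with at least one such event in
the window. The threshold is implemented inclusively (a bout of exactly
0.2 s counts): the defining sources state both "longer than 0.2 s" and that
events "completed in 0.2 s" are identifiable, and the inclusive reading
honors the latter. The remaining defaults were chosen once from the
simulator's kinematic repertoire (a semicircular roll pose scores 90°
curvature, so 45° splits roll from turn poses cleanly) and are not tuned to
any dataset.

`segment_bouts()` run-length encodes labels into half-open bouts (duration
= frames × frame interval), merges same-behavior bouts separated by
interruptions of at most `merge_gap_s` (absorbing the interruption — brief
mislabeled frames inside a roll should not split it), then relabels roll
bouts shorter than `min_roll_bout_s` to the preceding bout's behavior (the
following bout's at track start, `unknown` when alone) and re-merges.
Segmentation is idempotent, and bouts partition the track exactly; both are
tested properties.

## Escape metrics

`escape_metrics()` measures, per larva and stimulation window: roller
status (full-window and first-5-s variants), total roll time (bout overlap
with the window), first-roll onset and offset, the first crawl bout
starting after that roll, and the roll-offset-to-crawl-onset gap — all in
seconds from window onset. A roller that never resumed crawling before the
window closed gets the *window length* (30 s in the standard design) as its
crawl-onset value; this default scales with the configured window rather
than being hard-coded. Non-rollers get missing values for all roll-derived
fields and are excluded from latency samples — matching the convention that
latency ns are smaller than group sizes.

Population proportions (`binned_probability()`,
`probability_timeseries()`) use the Wilson score interval. The sources
state only "95% confidence interval"; Wilson was chosen over the normal
approximation because it is well-behaved at the proportions 0 and 1 that
all-or-none windows produce (its exact coverage at n = 100, p = 0.3 is
0.937, oscillating tightly around nominal — asserted in the tests by
summing binomial mass rather than simulating). Larvae not tracked through
the full stimulation window must be excluded before any metric;
`run_pipeline()` applies `filter_tracks()` and logs counts in/out.

## Statistics

The tests this literature reports are implemented from first principles
and cross-checked in the test suite against independent oracles
(brute-force pair counting, complete enumeration, base R):

* `chi2_2x2()` — uncorrected Pearson χ², df = 1. No Yates correction: the
  uncorrected formula reproduces the published statistics (35.51, 64.81,
  9.34) from tables reconstructed out of group sizes and rolling
  percentages, which validates the convention.
* `mann_whitney_u()` — midranks for ties; U = min(U₁, U₂) (the p-value is
  convention-independent); exact two-sided p by complete enumeration of
  group assignments when n₁+n₂ ≤ 12, otherwise a normal approximation with
  tie-corrected variance and a 0.5 continuity correction. The correction
  is needed for the approximation to track exact enumeration within 0.02
  at n₁ = n₂ = 6, and the empirical type-I error at nominal 0.05 stays
  within ±0.01 over 5,000 null simulations.
* `kruskal_wallis()` — tie-corrected H against χ²(k−1). For two groups, H
  equals the squared tie-corrected U z-score exactly (an algebraic
  identity asserted in the tests). When every observation is tied the
  correction degenerates; H is reported as 0 with a warning.
* `bonferroni()`, `cohens_d()` (pooled n−1-weighted SD), `wilson_ci()`.
* `normality_check()` — a Shapiro–Wilk screen; the pipeline defaults to
  the nonparametric branch regardless, since that is what escape-latency
  distributions call for.

All comparisons are two-sided.

## Stimulation-locked ΔF/F

`compute_dff()` follows the two-photon convention frame-for-frame:
fluorescence acquired at 30 fps is bin-averaged to 6 fps
(`downsample_trace()`); per trial, F₀ is the mean of the 10 frames
immediately before onset — 10 frames at 6 fps is 1.67 s, and frames, not
seconds, are treated as authoritative; F is averaged in consecutive 5-frame
bins spanning −5 s to +15 s around onset; ΔF/F = (F−F₀)/F₀ per bin; and the
per-ROI response averages the (standard three) trials. Bin timestamps are
bin centers, and `peak_dff()` searches bins whose centers lie in
[onset, onset + 15 s]. Binning is applied on time after alignment, so
onsets need not be frame-aligned. Trials with non-positive F₀ or
insufficient context are dropped with a warning, never imputed. ΔF/F is
invariant to multiplicative gain, and trial averaging shrinks peak noise by
≈ 1/√3 — both tested.

`dose_response()` summarizes peak ΔF/F against stimulation irradiance
(µW/mm², the standard series 0.04–1.4) with a least-squares line and R²,
exposed through `tidy()`/`glance()`/`autoplot()`.

## The synthetic larva: what it emulates, and what it does not

No tabular behavioral data accompany the studies this package targets, so
`simulate_population()` provides ground-truthed stand-ins with the
statistical structure the analysis assumes. Behavior is a stimulus-gated
**semi-Markov chain** — bout-level dwell distributions rather than
per-frame transitions, because every metric of interest is bout-level:

* outside stimulation, crawl dwells (gamma, mean 5 s, shape 3) alternate
  with brief turn/stop/hunch episodes (probabilities 0.5/0.35/0.15);
* at each stimulation onset a larva rolls with probability `p_roll`; a
  roller crawls for a uniform 0.3–1.5 s latency, then emits roll bouts
  with gamma durations (default mean 0.8 s, shape 3 — the short-bout
  regime; 1.4 s is the disinhibited regime), truncated below at the 0.2-s
  floor by resampling, separated by ~1-s crawl gaps with re-roll
  probability 0.5, and finishes the window crawling fast;
* any crawl inside a stimulation window runs at `stim_crawl_multiplier`
  (default 1.5) × the 0.7 mm/s baseline speed.

Rolling is rendered as a semicircular spine (90° three-chord curvature)
rotating at 360°/s while translating perpendicular to its tail→head chord —
satisfying the classifier's roll definition by construction; crawling as
axis-aligned translation with a 4% peristaltic length oscillation at
1.5 Hz; hunches contract the body 20% in place; turns deflect the head
quarter to 60° with slow forward creep. Gaussian positional noise (default
SD 0.02 mm per coordinate) is added last. State boundaries are snapped to
the frame grid so scripts tile the trial exactly, and each larva draws
from its own RNG stream derived from the master seed, making populations
bit-reproducible and stable under reordering. Where the defaults are not
dictated by published summary numbers (the 1.5× crawl multiplier, the
0.8-s/1.4-s bout regimes, the ~3-s calcium peak delay, the irradiance
series), they were set once to values a larval-behavior lab would call
realistic and are documented here rather than revisited.

What the generator does **not** emulate: published bout-duration
distributions or transition rates (none exist — the gamma family and the
chain's rates are this package's modeling choice, calibrated only to
printed summary regimes); contours or pixel-level appearance; multi-larva
collisions or arena walls; head/tail tracking flips; and any neuromuscular
realism. Passing recovery tests therefore demonstrates that the *analysis*
is correct and internally consistent — not that real larvae follow this
generative model.

`simulate_gcamp()` renders fluorescence as baseline × (1 + slope ×
irradiance × kernel) + noise, with a double-exponential kernel (rise 0.8 s,
decay 6 s) normalized to peak 1. Because the two time constants fix the
kernel's natural peak time, the configured `peak_delay_s` (default 3 s) is
honored by shifting the kernel onset; a peak delay earlier than the
natural peak is rejected as ill-posed, as is decay ≤ rise. True peak ΔF/F
per irradiance and the true peak time are returned with the traces, so
parameter-recovery tests need no re-derivation.

## Numerical conventions and degenerate inputs

Seconds for time, mm for coordinates, degrees for angles; probabilities are
fractions internally and percentages only at presentation. Half-open
intervals everywhere; boundary comparisons carry a 1e-9 slack so exact
0.2-s bouts are kept. Empty inputs return empty outputs where that is
meaningful (zero larvae, empty track list) and error where it is not (no
durations, no usable calcium trials). An all-tied Kruskal–Wallis, a
zero-pooled-SD Cohen's d, and a zero chi-square margin are each rejected or
flagged explicitly rather than returning NaN.

## Problem sizes

The test suite runs a 40-larva default-noise population for module tests; a
1,000-larva low-noise population for end-to-end recovery of the rolling
probability (binomial 99% CI) and the bout-duration mean (within 10%,
gamma fit); 150 larvae for frame-level roll precision/recall (≥ 0.9);
5,000 null simulations for the Mann–Whitney type-I error; and 500 script
draws against a 4,000-draw independent chain simulation for roll-occupancy
calibration. `scripts/acceptance.R` uses 600 larvae for its recovery run.
These sizes give Monte-Carlo error comfortably inside each stated bound.

## Known limitations

* The rule-based classifier is a declared substitute: its frame-level
  agreement with the trained classifiers on *real* tracking data is
  unknown and unknowable without that data. Its error rates here
  (≤ 10% roll false-positive/negative on synthetic data) characterize
  generator–classifier self-consistency.
* Whether a roll bout interrupted by sub-0.2-s non-roll frames was merged
  in the original analyses is unstated; this package merges across gaps
  ≤ 0.1 s by default, configurable to 0 to disable.
* Whether original crawl-onset latency samples include the 30-s defaults
  is unstated; `escape_metrics()` reports the default values and leaves
  inclusion to the caller.
* Track-level head/tail orientation is trusted as given; real MWT data can
  flip it.
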