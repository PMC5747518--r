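---
title: "Models and numerical conventions in stopgo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical conventions in stopgo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stopgo)
```

`stopgo` analyses Ca²⁺-regulated stop-and-go T cell motility: track-derived
motility statistics, ratiometric Ca²⁺ traces from tandem green/red
indicators, spatiotemporal transient detection, Ca²⁺-rise-triggered
velocity averaging, and nonparametric group comparison. This vignette is
the package's account of the underlying models, the tunable parameters and
their defaults, the design decisions taken where conventions were open,
and what the synthetic-data tests do and do not establish. It states no
empirical result that the test suite does not itself compute.

## The motility model

Each simulated cell is a two-state process sampled every `dt_s` seconds.

**GO.** The cell moves at a per-cell speed drawn once from a lognormal
with mean `mean_speed_um_min` and coefficient of variation `speed_cv`.
Its heading performs a persistent random walk with decorrelation time
`persistence_s`: in 2D the heading angle receives Gaussian noise of
variance `2·dt/persistence_s` per step, which makes the step-to-step
correlation exactly `exp(-dt/persistence_s)`. In 3D the same additive
recipe is only approximate and leaves residual correlation when the noise
is large, so the new heading is instead drawn from a von Mises–Fisher
distribution around the old one, with concentration chosen (by inverting
the Langevin function) so the per-step correlation is again exactly
`exp(-dt/persistence_s)`. Because successive rotations are independent and
azimuthally symmetric, the heading autocorrelation is exactly exponential
in every regime — including the Brownian limit `persistence_s ≪ dt`, where
the known-motility-coefficient recovery test depends on steps being truly
independent.

**PAUSE.** Pauses start as a Poisson process at `pause_rate_per_min` and
end after an exponential dwell of mean `pause_mean_s` (the pause-duration
distribution is not constrained by published data; exponential is an
assumption, not an inference). During a pause the cell jitters at a speed
drawn uniformly below 1 µm/min — always under the 2 µm/min arrest
threshold. Two deliberate refinements within that band:

- the *entry* step of each pause is drawn from [0, 0.05] µm/min, so the
  pause's velocity minimum sits deterministically at its onset. Without
  this, "the transient peak precedes the velocity minimum by `ca_lead_s`"
  would reference a uniformly random frame inside the pause and the
  rise-triggered average could not recover a sharp lag;
- on pause *exit* the heading is redrawn uniformly. Pausing in T cells
  coincides with turning; coupling the two is what makes a reduced pause
  rate produce slower directionality decay and unchanged peak velocity —
  the channel-block contrast the acceptance suite checks.

Default parameters and where they come from: mean speed 11 µm/min and the
arrest-coefficient scale 0.02–0.16 match published lymph-node values;
`pause_rate_per_min = 0.2` with `pause_mean_s = 30` s gives a two-state
pause occupancy `r·m/(1+r·m) ≈ 0.09`, inside that range; `dt_s = 5` s and
600 s recordings match typical two-photon acquisition; `persistence_s =
240` s is chosen so fitted directionality decay times land in the
published few-hundred-second range; `ca_lead_s = 5` s reproduces the
published 5 s lead of the Ca²⁺ rise over the velocity minimum;
sparkles default to 2 µm² and 2 s, global transient amplitude to 0.5 above
a unit baseline, and tdTomato bleach to 25% (the middle of the reported
20–30% decline). These are the stated world of the generator; they were
fixed before the acceptance measurements and are not tuned to test
outcomes.

## Calcium trace synthesis

Only the red channel bleaches appreciably: `R(t) = R₀·(1 −
bleach_fraction·t/T)` with multiplicative noise (`trace_noise_cv`,
settable to 0 for closed-form checks). The green baseline is flat, so the
*raw* G/R ratio drifts up by `1/(1 − bleach_fraction)` over a recording
and flattens only after the red-only linear correction — this mirrors the
analysis convention in which tdTomato bleaching is corrected "as a linear
function of time" while GCaMP6f is left untouched. Each coupled pause
receives a flat-topped transient (smoothstep edges one frame wide) whose
peak is placed `ca_lead_s` before the pause's velocity minimum and whose
plateau extends to the pause end, so elevation duration tracks pause
duration; sparkles are temporal Gaussians with FWHM `sparkle_duration_s`,
Poisson in time and uncoupled to motility. The true peak normalized ratio
is `1 + transient_amplitude` exactly, which the tests verify.

## Track statistics: conventions

- Instantaneous velocity uses consecutive frames, no smoothing.
- Thresholds are strict (`< 2`, `< 7` µm/min, `> 1.10`), matching how the
  quantities are defined in the literature this package follows; arrest at
  exactly the threshold is counted as moving.
- Turn angles skip steps shorter than `min_step_um = 0.5` µm
  (noise-dominated headings) and span the gap.
- Mean track velocity is the mean of instantaneous velocities, not net
  displacement over time.
- The directionality fit `r(t) = r_∞ + (1−r_∞)e^{−t/τ}` runs on the
  track-averaged curve with `r_∞` free in [0, 1]. The fitted τ is a
  property of this estimator, not the heading persistence time: for a
  persistent random walk it comes out roughly four times
  `persistence_s`. The parameter-recovery test therefore compares the
  simulation fit against the same exponential fit applied to the analytic
  PRW decay curve `min(1, sqrt(MSD(t))/(v·t))` — the two agree to within
  a few percent — rather than against `persistence_s` itself, which no
  estimator of this form could match.
- MSD averages all overlapping frame pairs (lower variance than disjoint
  windows); the motility coefficient uses a zero-intercept fit over the
  first 25% of lags and `M = slope/(2·dim)`. Both conventions are recorded
  in the returned object.

## Ratiometric processing

Bleach correction fits `a + b·t` per cell to its own red trace (pooling
across cells is not assumed) and divides by the normalized line, keeping
the correction multiplicative — the natural model for fluorophore loss —
and idempotent. A fitted decline above 60% triggers a warning (far outside
the 20–30% regime the linearization is meant for); a non-positive
intercept is an error. `R₀` is the mean of the first five ratios of each
trace; note that a transient inside those five frames contaminates `R₀`,
which is faithful to the convention rather than a defect. Velocity is
paired with the ratio at the earlier frame of each displacement interval.

## Transient detection

Autofluorescent bodies are bright in essentially every frame, so the
per-pixel temporal 10th percentile isolates them from transients (which
occupy few frames) and from passing cells; pixels above
`median + 5·MAD` of that percentile image are set to background in both
channels and returned as an audit mask. Detection thresholds default to
`median + 5·MAD-SD` of the masked green channel — a reproducible stand-in
for the manual intensity thresholding of interactive workflows; absolute
thresholds are accepted. Components use full 26-connectivity in XY-T
(implemented in C++ with union-find); `>10` voxels is strict, the 2 s
minimum duration is inclusive of the frame extent (a 4-frame event at
0.5 s/frame lasts 2.0 s and passes). Diameters are four times the square
root of the eigenvalues of the intensity-weighted spatial covariance
(exact for a uniform disc, less noise-sensitive than bounding boxes);
area is `π(d_x/2)(d_y/2)`; single-voxel extents floor at one pixel. The
sparkle/cell-wide boundary, 20 µm², is a documented default chosen near a
T cell cross-section — the published distinction is visual, not numeric.

A resolution caveat quantified by the acceptance suite: at 0.65 µm/px a
2 µm² sparkle spans about five pixels, so a single sparkle's measured area
carries roughly one pixel-area (~20%) of discretization granularity even
without noise. Median area accuracy is well within ±25% and cell-wide
(40 µm²) events are individually within ±25%, but individual sparkle areas
can exceed that bound; the acceptance test asserts exactly this
decomposition rather than pretending per-sparkle accuracy the pixel grid
cannot deliver.

## Event coupling

Rise onsets are upward crossings of the same 1.10 normalized-ratio level
used for elevated/basal classification (internal consistency; a
derivative-based detector was rejected as noisier at 5–20 s frame
intervals), debounced at 30 s. Velocity segments are resampled onto the
relative-time grid by nearest frame — interpolation at these frame
intervals would manufacture data. The default window is −40…+40 s with a
−30…−10 s baseline; the minimum of the mean curve is searched in 0…+20 s,
and each event contributes its own baseline to a paired two-tailed t-test.
If the paired differences are numerically constant (a degenerate but valid
synthetic case) the p value is reported as 0 or 1 directly instead of
failing inside the t-test.

## Group statistics

Mann-Whitney U uses the exact null distribution when `min(n) ≤ 8` with no
ties and a tie-corrected normal approximation with continuity correction
otherwise; which route ran is reported. The Hodges-Lehmann estimate is the
median of all pairwise differences with confidence limits from the
Mann-Whitney order-statistic inversion. Pairwise p values are unadjusted
by default (matching the pairwise reporting style of the motility
literature); Holm adjustment is available behind a flag. Cells are pooled
across animals/donors — no mixed-effects nesting — which is a known
limitation, not an oversight.

## File formats

Tracks round-trip through a flat CSV schema (`cell_id, frame, t_s, x_um,
y_um[, z_um][, green, red][, group]`); non-monotone time is a parse error
naming the row, non-uniform sampling beyond 1% drops the track with a
logged reason. Image stacks round-trip through a minimal baseline TIFF
codec written in-package (uncompressed 16-bit grayscale, channel-
interleaved pages, pixel size and frame interval in ImageDescription):
no R TIFF reader is available in the supported dependency set, and the
codec is deliberately restricted to the baseline subset it writes.
Configurations use a flat `key: value` text format. Every pipeline output
carries the seed and an MD5 config hash, and `manifest.json` records
enough to reproduce a run.

## What the synthetic tests establish — and what they do not

The generator reproduces the statistical structure the analysis consumes:
two-state kinematics, exponential heading decorrelation, pause-locked
ratio transients with a known lead, linear red bleach, and shot-noise
images with known event geometry. It does not emulate cell shape changes,
z-drift, motion blur, segmentation error, indicator saturation and
kinetics, spatial heterogeneity of the lymph node, or cell-cell contact.
A green suite therefore establishes that the estimators are correct on
data obeying their assumptions and that detection tolerates shot noise
and stationary clutter at realistic SNR — not that the pipeline is robust
to every artefact of live two-photon imaging.

## Known limitations

- Tracks are taken as given; detection/linking (tracking) is out of scope.
- Image-stack detection is XY-T only; tracks may be 3D but rendered
  stacks are 2D+time.
- The channel-block condition is modelled purely as a reduced pause rate;
  there is no channel biophysics.
- Fitted directionality τ values depend on recording length (the
  exponential is a convenient summary, not the true functional form of
  PRW decay); compare τ only across equal-length recordings.
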