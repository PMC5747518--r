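# stopgo

Quantitative analysis of Ca²⁺-regulated "stop-and-go" T cell motility.

T cells scanning lymph nodes for antigen alternate between fast, persistent
crawling and spontaneous pauses. Store-operated Ca²⁺ entry through Orai1
channels triggers those pauses: cytosolic Ca²⁺ elevations — reported by
ratiometric tandem indicators such as Salsa6f (GCaMP6f fused to tdTomato) —
precede the drop in cell velocity, and blocking the channel reduces pause
frequency without changing peak speed. `stopgo` packages the complete
analysis chain needed to quantify this behaviour from cell tracks and
two-channel time-lapse imaging, together with a synthetic-data generator
with known ground truth for validating every step.

## What it computes

**Track statistics** (for tracks `x(t)` sampled at interval `Δt`):

- instantaneous velocity `v_i = ‖x_{i+1} − x_i‖ / Δt` (µm/min, no smoothing);
- arrest coefficient = fraction of steps with `v < 2` µm/min; pause
  durations as maximal sub-threshold runs; coefficient of variation
  `100·SD(v)/mean(v)`; turn angles; per-track mean/max/min velocity;
- directionality ratio (displacement/path length) vs elapsed time, with
  decay time τ from `r(t) = r_∞ + (1 − r_∞)·e^{−t/τ}`;
- mean-squared displacement over all overlapping frame pairs and the
  motility coefficient `M` from `MSD = 2·dim·M·t` fitted over the first
  quarter of lags.

**Ratiometric Ca²⁺ traces**: linear photobleach correction of the red
channel (`R_corr = R_raw / (1 + (b/a)t)` from a least-squares line
`a + bt`), G/R ratio, normalization to `R₀` (mean of the first five
ratios), elevated/basal classification at normalized ratio 1.10, quadrant
occupancy of the velocity-ratio scatter, and state-conditional velocity.

**Transient detection** in two-channel XY-T stacks: masking of stationary
autofluorescent bodies via the per-pixel temporal 10th percentile,
connected components of suprathreshold green voxels (26-connectivity with
time as the third axis), filters `>10` voxels and `≥2` s duration,
ellipse-equivalent diameters from the intensity-weighted covariance,
sparkle vs cell-wide classification at 20 µm², and integrated intensities
normalized to the green-channel SD.

**Event coupling**: Ca²⁺-rise onset detection (upward 1.10 crossings with
30 s debounce) and rise-triggered averaging of instantaneous velocity with
a paired t-test of the post-rise minimum against a −30…−10 s baseline;
pooled Spearman correlation of velocity vs ratio.

**Group statistics**: Mann-Whitney U (exact for small samples, tie-corrected
normal approximation otherwise) and the Hodges-Lehmann shift estimate with
order-statistic confidence intervals.

**Synthetic data**: a two-state persistent-random-walk simulator
(GO/PAUSE, exponential dwell, heading decorrelation time `persistence_s`),
coupled G/R trace synthesis (transient peak leads each pause's velocity
minimum by `ca_lead_s`; linear tdTomato bleach), and a rasterizer that
renders tracks and seeded transients into 16-bit two-channel image stacks
with shot noise and autofluorescent bodies.

## Worked example

```r
library(stopgo)
cfg <- sim_config(n_cells = 50, duration_s = 600, dt_s = 5, seed = 7)
sim <- simulate_calcium(simulate_tracks(cfg))

summ <- summarize_tracks(sim$tracks)
msd  <- msd_curve(sim$tracks)
dirc <- directionality_ratio_curve(sim$tracks)
sc   <- velocity_ratio_scatter(sim$tracks)
eta  <- event_triggered_average(sim$tracks)

cat(sprintf("mean track velocity: %.1f +- %.1f um/min (n = %d)\n",
            mean(summ$mean_velocity_um_min),
            sd(summ$mean_velocity_um_min) / sqrt(nrow(summ)), nrow(summ)))
cat(sprintf("arrest coefficient:  %.3f +- %.3f\n",
            mean(summ$arrest_coefficient),
            sd(summ$arrest_coefficient) / sqrt(nrow(summ))))
cat(sprintf("motility coefficient: %.1f um^2/min\n",
            msd$motility_coefficient_um2_min))
cat(sprintf("directionality decay tau: %.0f s\n", dirc$tau_s))
cat(sprintf("velocity vs G/R ratio: Spearman rho = %.2f, p = %.2g, n = %d pairs\n",
            sc$rho, sc$p_value, sc$n))
cat(sprintf("rise-aligned velocity minimum at %+.0f s (n = %d events, p = %.2g)\n",
            eta$t_min_s, eta$n_events, eta$p_value))
```

Output:

```
mean track velocity: 9.7 +- 0.4 um/min (n = 50)
arrest coefficient:  0.110 +- 0.011
motility coefficient: 26.1 um^2/min
directionality decay tau: 894 s
velocity vs G/R ratio: Spearman rho = -0.24, p = 2.9e-78, n = 6000 pairs
rise-aligned velocity minimum at +5 s (n = 163 events, p = 1.1e-18)
```

Reading: cells crawl at ~10 µm/min and spend ~11% of steps arrested
(`< 2` µm/min); spreading is diffusive with `M ≈ 26` µm²/min; velocity and
Ca²⁺ ratio are negatively correlated; and aligning velocity on detected
Ca²⁺ rises places the mean velocity minimum 5 s after the rise — the Ca²⁺
signal leads the pause, exactly the ground truth the generator encoded
(`ca_lead_s = 5`).

The same pipeline runs from the command line:

```sh
Rscript inst/cli/stopgo run --out results_demo --seed 7
Rscript inst/cli/stopgo detect --stack field.tif --out results_detect
```

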