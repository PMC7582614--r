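---
title: "Methods: PPG-only blood pressure estimation in ppgbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PPG-only blood pressure estimation in ppgbp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppgbp)
```

## The problem and the model

Continuous, cuffless blood-pressure monitoring from a single optical
sensor is attractive because PPG sensors are ubiquitous in wearables while
ECG electrodes and pressure cuffs are not. The premise of the feature-based
approach implemented here is that the morphology of a single PPG cardiac
cycle — how fast the systolic upstroke rises, where the dicrotic notch
sits, how the areas under the rising and falling limbs partition — carries
enough information about vascular state to regress systolic and diastolic
pressure directly, one estimate per heartbeat.

The pipeline is: band-limit and normalize the waveform, locate per-cycle
fiducial points, compute 59 morphological features per cycle, screen them
with a distribution-similarity index, and regress (SBP, DBP) with a fully
connected network. Each stage is exported and individually testable; this
vignette records the scientific and numerical choices behind each one.

## Preprocessing

**Band-limiting.** `bandlimit()` zeroes DFT bins whose frequency falls
outside `[low_cut_hz, high_cut_hz]` and inverts the transform. Bins are
zeroed symmetrically (bin *k* and *N−k*) so the restored signal is exactly
real. The upper edge defaults to 8 Hz, which keeps the pulse morphology
(fundamental ~1–2 Hz plus a handful of harmonics) and removes
high-frequency noise; the bound is treated as *inclusive*, and because a
passband starting at 0 Hz excludes nothing at the low end, no high-pass is
applied by default — `low_cut_hz` is an escape hatch for users who want to
suppress baseline wander in the frequency domain rather than rely on the
per-segment normalization. The operation is idempotent, which the tests
assert.

A hard spectral cutoff is a brick-wall filter, and brick-wall filters ring
at discontinuities. The practical consequence — visible during
development — is that a record whose implicit periodic extension jumps at
the record boundary contaminates its edge cycles. The synthetic generator
therefore emits records trimmed to whole cardiac cycles (see below); users
filtering real records should expect the first and last beats to be the
least reliable.

**Normalization.** `minmax_normalize()` maps each record to `[0, 1]`; a
constant segment has no morphology to normalize and is rejected as a
degenerate input rather than silently returned.

**Derivatives.** First and second derivatives (dPPG, sdPPG) use central
differences scaled by the sampling interval, one-sided at the record ends.
Central differences are the lowest-error scheme available at this cost and
matter here because fiducial detection reads extrema of these signals.

## Fiducial detection

Six landmarks are located per cycle, in a fixed dependency order:

1. **Systolic peaks** — regions where the normalized PPG exceeds its
   0.75 s moving average, each contributing its maximum. Candidates closer
   together than 0.7 of the dominant period are pruned keeping the taller
   peak; the dominant period is the smallest autocorrelation lag in the
   plausible heart-rate band (0.33–2.0 s, i.e. 30–180 bpm) reaching 90% of
   the band maximum. The autocorrelation step is what lets the same
   detector work at 50 and at 100 bpm without retuning: a fixed refractory
   distance either swallows genuine beats or admits dicrotic waves.
2. **Onset/offset valleys** — the minimum strictly between consecutive
   peaks (ties to the earliest index, for determinism); the segmentation
   wrapper adds the boundary valleys before the first and after the last
   peak so every detected beat yields a segment.
3. **Slope extrema** — argmax of dPPG between onset and peak, argmin
   between peak and offset.
4. **Dicrotic notch** — the largest interior local maximum of sdPPG
   strictly between peak and offset (ties to the earliest). A gate
   precedes this rule: a notch is only reported when dPPG has a strict
   interior local maximum in the window. The gate is not cosmetic — the
   descending limb of *any* single-lobed pulse has a positive-curvature
   maximum, so the bare "largest sdPPG local max" rule would fabricate a
   notch on notchless cycles; an interior dPPG maximum exists precisely
   when a secondary (dicrotic) wave perturbs the descent.

Cycles are cut valley-to-valley as closed spans sharing the boundary
sample, with 1-based indices throughout (the R convention). Abnormal
cycles are removed by configurable plausibility bounds — SBP in 80–180,
DBP in 60–130, pulse pressure ≥ 20 mmHg, duration 0.33–2.0 s, all six
fiducials present and ordered. These bounds are explicit stand-ins for the
prescreening conventions of the intensive-care literature; because a
segment survives only if it violates *no* rule, the surviving set is
independent of rule order, which the tests verify by applying the rules
singly and intersecting.

## The 59 features and their conventions

Time features are fiducial index differences over the sampling rate;
areas are trapezoidal integrals of the named signal between the named
fiducials; slopes are intensity differences over time differences;
intensity features read the named signal at the named fiducial. Three
conventions were genuinely open and are fixed as follows:

* `t1`–`t4` are the durations of the spans bounding the areas `S1`–`S4`
  (onset→max-slope, max-slope→peak, peak→notch, notch→offset). This is the
  only reading under which the duration-ratio features are dimensionally
  coherent: systolic duration `t1+t2+t3`, diastolic `t4`, and the
  identities `RSC + RDC = 1` and `hr = 60/(t1+t2+t3+t4)` hold exactly.
  `t5`–`t8` are the ascending/descending durations on dPPG and sdPPG
  (two of these carried an identical printed definition in the source
  table; the mapping here assigns `t6` to dPPG and `t8` to sdPPG descent).
* Derivative-signal features (`d`/`sd` prefixes) anchor on the fragment's
  own extrema — peak = argmax, valley = argmin within the cycle — because
  derivative waveforms have no independently defined onset/peak landmarks.
* Standardization uses the population (divide-by-*n*) standard deviation,
  matching the two-point convention `[1, 3] → [−1, 1]`; Z-scores are not
  clipped to any range (they are unbounded by definition). Cycles missing
  any selected feature (absent notch, zero denominator) are dropped before
  training and counted in the run manifest, since the network requires
  complete vectors.

## The γ screening index

For a standardized feature, γ is the mean absolute difference between the
empirical probability mass of the feature rounded to `k` decimals and the
standard-normal mass of the bin `[v, v + 10^-k)`, over the grid
`v = −C, −C+10^-k, …, +C` (defaults `k = 1`, `C = 3`: 61 bins). Low γ
means a normal-shaped marginal — the screening rationale being that
pressure itself is approximately normal over a large corpus, so features
whose distribution matches are better-behaved regression inputs. Mass
outside the window is ignored (not renormalized), rounding is
half-away-from-zero for platform stability, and inputs that are not
actually standardized (|mean| > 0.05 or |sd − 1| > 0.05) are rejected.
The printed definition of this index in the source literature uses
mutually inconsistent symbols for the grid step and span; the
reconstruction above is the only one consistent with its stated intent
(one-decimal precision, μ ± 3σ window, mean absolute error), and it is
pinned by tests against brute-force enumeration over all 61 bins.

Selection takes the `n_lowest = 32` features by ascending γ (ties broken
by name), with two documented overrides: `S1` and `S2` are forced in and
`sdAS`, `sdDS` forced out — the areas are classical pressure correlates
with only slightly higher γ, and regressors fed them outperform those fed
the two derivative slopes. The package ships the reference γ table
computed on a ~2.18-million-cycle ICU corpus (`reference_gamma()`);
ranking it reproduces the published 32-feature working set exactly, which
is an acceptance test.

## The regressor

`train_regressor()` implements the fully connected network directly in R:
affine layers with ReLU hidden activations and an identity 2-unit output,
He initialization, and the Nadam update (Adam moments with a
Nesterov-style lookahead on the first moment). The default architecture
is the full-scale 2048/4096/8192/2048; every width is configurable, and
desk-scale work uses networks like 32/32, which recover an affine
morphology→pressure map to a fraction of a mmHg. Choices the architecture
leaves open, fixed here and recorded in the config object: MSE as the
training objective (same optimum as the monitored RMSE, stabler
gradients), mini-batch size 512, learning rate 1e-3, early stopping on
validation RMSE with patience 10 within a 500-epoch budget, output bias
initialized at the training-label means. The split is by cycle (70/20/10
train/test/validation), mirroring the reference procedure; note that
cycle-wise splitting of multi-subject data leaks subject identity across
parts, so per-subject splits should be used when subject labels exist.
The forward pass is pinned against a loop-based oracle on random small
networks, and training is reproducible given the config seed.

## Evaluation

Errors are `estimate − truth` throughout (the Bland–Altman difference uses
the same sign). The report assembles RMSE, MAE, ME ± SD, Pearson r,
limits of agreement μ ± 1.96σ with the within-LOA percentage, cumulative
percentages of |error| ≤ 5/10/15 mmHg (inclusive comparisons), the BHS
grade (best grade whose three thresholds are all met; D otherwise) and
the AAMI verdict (|ME| ≤ 5 mmHg and SD ≤ 8 mmHg). Standard deviations use
the population convention for consistency with the feature module; both
are configurable. Every field is tested against an independent loop-based
recomputation on random inputs, and the grading operations reproduce the
published worked examples.

## The synthetic generator: what it emulates and what it does not

`generate_record()` models each cardiac cycle as two positive Gaussian
lobes on a shared baseline — a systolic wave (centre 0.30 of the cycle,
width 0.11) and a dicrotic wave (centre `notch_delay_fraction`, default
0.62, width 0.09, relative height `notch_relative_intensity`, default
0.4). This is the minimal shape with a systolic peak, a detectable notch
between the lobes, and a diastolic wave. Baseline wander is a slow
sinusoid (< 0.5 Hz), high-frequency noise a fast sinusoid (> 8 Hz) plus
optional white noise; both superpose additively so the zero-noise record
equals the clean pulse train exactly. Records are trimmed to whole
cycles, and phantom neighbour cycles supply mid-stream tails at both
edges, so the FFT filter sees no wrap discontinuity.

Ground truth is what makes the generator first-class: per cycle it
reports all six fiducial sample indices — slope extrema and notch located
on the *closed-form* derivatives of the two-lobe model, independent of
the package's discrete detection chain — plus the morphology parameters
and pressure labels. Labels are an affine map of (cycle duration,
amplitude, dicrotic intensity) plus Gaussian noise, with defaults placed
at ~122/80 mmHg for the default morphology; pulse pressure is floored at
5 mmHg (flagged in the table) so SBP > DBP holds for every cycle. The ABP
channel is the clean train rescaled per cycle so its maximum/minimum equal
the mapped SBP/DBP, letting label extraction be tested end-to-end.
`generate_feature_dataset()` skips the waveform entirely and emits
correlated-Gaussian feature rows with exactly-affine labels, the
controlled task on which regressor parameter recovery is measured against
the known noise floor.

What passing tests on this generator do **not** show: robustness to real
PPG phenomena — motion artifacts, varying pulse shapes across subjects
and diseases, arrhythmic beats, sensor saturation, or notches that
manifest as a bare inflection rather than a wave. The noise-free
fiducial-validation configurations deliberately draw morphologies with a
genuine dicrotic dip (relative intensity 0.35–0.6, delay 0.55–0.72 of the
cycle, 50–100 bpm), because sample-accurate ground-truth comparison is
only meaningful where the landmark is well-defined.

## Problem sizes and numerical tolerances

The shipped tests validate: fiducial recovery on 100 random noise-free
10 s records at 125 Hz (every cycle found, every fiducial within ±3
samples of closed-form ground truth); γ identities by brute-force
enumeration and on a 10⁶-sample normal column (γ < 0.003); feature
algebra to 1e-9 against hand-computed trapezoids on a 21-sample toy
cycle; forward-pass equivalence to 1e-6 on 100 random networks; report
fields to 1e-9 on 1000 random trials; and regressor recovery at n = 10⁴
(validation RMSE < 1 mmHg noiseless, 2.4–3.8 mmHg at a 3 mmHg noise
floor) with two hidden layers of 32 — sizes chosen so the whole suite
runs in a couple of minutes on one core while still exercising every
claim. The full-scale architecture changes capacity, not code paths.

## Known limitations

* The γ index screens for distribution shape only; it does not measure
  correlation with pressure, and a feature can be perfectly normal and
  perfectly uninformative.
* Training labels derived from per-cycle ABP extrema inherit ABP artifact
  sensitivity on real data; the generator sidesteps this by construction.
* The brick-wall filter is faithful to the method but is not the best
  denoiser available; wavelet or zero-phase IIR alternatives are out of
  scope.
* No arrhythmia handling: the plausibility screen removes grossly
  abnormal cycles but does not classify beats.
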