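---
title: "Decoding visual stimuli from EEG phase and power: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding visual stimuli from EEG phase and power: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phasedecode)
```

## The scientific question

When a person views one of a small set of visual stimuli — here, five letters
of the alphabet — the stimulus identity is partially recoverable from the
single-trial EEG. Two candidate carriers of that information are the
*instantaneous power* (amplitude envelope) and the *instantaneous phase* of
band-limited oscillations, particularly in the theta (4–8 Hz) and alpha
(8–14 Hz) ranges over parieto-occipital cortex. `phasedecode` implements the
full analysis needed to ask which carrier, which frequency band, which
latency window and which electrodes support decoding — and to decide, with a
selection-aware permutation test, when an observed decoding accuracy is more
than chance.

The pipeline is:

1. epoched, baseline-corrected multichannel EEG (500 Hz, −500…1000 ms
   around stimulus onset, five classes);
2. Kaiser-window linear-phase FIR band filtering into the six canonical
   rhythm bands;
3. the Hilbert analytic signal per trial and channel, giving amplitude
   `A(t)` and phase `P(t)` sequences;
4. per-electrode five-class decoding of 200 ms feature windows with a
   Gaussian-kernel SVM under stratified 30-fold cross-validation;
5. a shuffled-label **max-statistic** permutation null, a normal fit with a
   Kolmogorov–Smirnov diagnostic, three-sigma thresholds, band-by-time
   `log10(1/p)` maps and scalp topographies.

Because the recordings this design targets are not redistributable, the
package ships a synthetic generator that reproduces the *statistical
structure* the analysis assumes, so every stage is testable end-to-end.

## The synthetic generator: what it emulates, and what it does not

`generate_dataset(synth_config(...))` draws `n_per_class × 5` epochs
(default 90 × 5 = 450) of 64-channel EEG-like data:

* **Background**: Gaussian noise spectrally shaped to `1/f^alpha`
  (default `alpha = 1`), independent across channels plus a shared
  common-mode component (mixing weight 0.3) to mimic volume conduction;
  per-channel RMS 10 µV.
* **Phase code** (`coding = "phase"`): at five target channels (PO7, PO8,
  O1, Oz, O2), within the informative window 100–600 ms, a carrier-band
  oscillation `A·env(t)·cos(2πf₀(t − t_ref) + φ_class + jitter)` with
  `f₀` the band midpoint (6 Hz for the default theta carrier), `env` a
  raised-cosine ramped (50 ms) envelope, and per-trial wrapped-normal phase
  jitter (SD 0.5 rad). The five class offsets are `2πk/5`. The envelope is
  identical across classes, so *power carries no class information* — a
  property the tests verify by ANOVA on single-trial band power.
* **Power code** (`coding = "power"`): the class-`k` amplitude is scaled by
  `1 + k·amp_step` with a per-trial uniformly random carrier phase, so
  *phase carries no class information*.
* **No code** (`coding = "none"`): labels are drawn independently of the
  data; this is the empirical-chance condition.

Design choices worth recording:

* **Phase reference.** The carrier is referenced to the code-window
  midpoint (`t_ref` = 350 ms), so the Hilbert phase measured mid-window
  equals the class offset. Without a reference, the instantaneous phase of
  a 6 Hz carrier advances a full cycle every 167 ms and "the class phase"
  would be ill-defined as a testable quantity.
* **What `snr` means.** `snr` is the ratio of the code oscillation's RMS
  (over the code window) to the background RMS *within the carrier band*
  at the target channels. At the default `snr = 1` the single-trial phase
  concentration (resultant length ≈ 0.6 at the best electrode) is partial,
  as stimulus-locked phase concentration in real EEG is.
* **Power-code step.** The spec of the amplitude code leaves the per-class
  step free; the default `amp_step = 0.4·snr` was fixed once, at design
  time, so that the amplitude code at `snr = 1` is decodable at roughly
  30% best-electrode accuracy — the magnitude of band-power effects this
  analysis is meant to detect — rather than being either undetectable or
  trivially separable.
* **What it does *not* emulate**: no biophysical forward model, no
  eye-blink/EMG artifacts, no inter-subject variability in code latency or
  topography, no cross-frequency coupling, and the background is Gaussian
  (real EEG has heavier tails and nonstationarities). Passing tests on this
  generator therefore validate the *pipeline's statistical machinery* —
  calibration of the chance level, selection-aware thresholds, carrier
  dissociation — not the effect sizes obtainable from real recordings.

## Filtering: the transition-width trade-off

The band filters are classic Kaiser windowed-sinc designs: ideal bandpass
cutoffs at the transition-band midpoints, window β and length from the
standard Kaiser equations for the requested stopband attenuation (default
30 dB, with a 2 dB design margin so the attenuation holds *at* the stop
edges), length forced odd so the filter is exactly linear-phase.

A hard constraint appears at 500 Hz: a 30 dB design with the canonical
**1 Hz transition** needs ≈770 taps — longer than a 1.5 s epoch (750
samples). Filtering an epoch with such a kernel leaves no sample free of
edge influence. The package therefore separates two uses:

* `design_band_fir()` defaults to the canonical 1 Hz transition and is the
  object of the frequency-response tests (−30 dB everywhere at ≥1 Hz
  outside the passband, passband ripple within the Kaiser bound, constant
  group delay `(L−1)/2`);
* pipeline-level filtering (`filter_band()`, used by the significance
  maps) defaults to a **3 Hz transition** (257 taps, 128-sample group
  delay). After delay compensation the first and last 128 samples
  (≈256 ms) are marked invalid, leaving −244…744 ms usable — a superset of
  every analysis window the sliding grid ever touches (−100…700 ms).
  `extract_window()` refuses windows overlapping the invalid region, so
  filter-edge phase artifacts cannot silently enter a feature matrix.

For the delta band (1–4 Hz) a 3 Hz transition would cross 0 Hz; the low
cutoff is then placed at `low_hz/2` and the design is flagged
(`low_relaxed`, with a warning): the stopband guarantee holds on the high
side only. The alternative — excluding delta from the band-by-time map —
seemed worse than a documented, flagged relaxation.

Filtering is a single forward pass with group-delay compensation, not
forward–backward: for an exactly linear-phase FIR the compensated output
has zero net phase distortion, and a single pass keeps the effective
attenuation at its design value.

## Features

`analytic_signal()` computes the discrete analytic signal per trial and
channel over the *full* epoch (one-sided spectrum doubling in the frequency
domain), and windows are sliced afterwards — computing the Hilbert
transform per window would re-introduce edge effects at every window
boundary. The real part is forced to equal the input exactly; the imaginary
part is tested against the exact periodic principal-value convolution
kernel.

Phase features default to the **raw angle** in (−π, π], matching the
definition of the phase sequence as the argument of the analytic signal. The
angle presents a 2π wrap discontinuity to the kernel; an optional
`sincos` encoding (interleaved cos/sin, 2× features) removes it. Both are
exposed; the raw angle — the phase sequence proper — is the default. Power
features are the amplitude sequence `A(t)`; an optional per-feature
z-scoring flag exists (`standardize`) but is off by default: phase features
are bounded by construction, and amplitude features are left on their
native microvolt scale.

Window grids: the sliding grid is sixteen 200 ms windows starting −100,
−60, …, 500 ms (midpoints 0…600 ms); the growing grid is three hundred
windows anchored at 0 ms with lengths 2, 4, …, 600 ms. The growing "2 ms
step" is interpreted as stepping the window *length* with the start fixed
at stimulus onset — the reading consistent with asking when information has
*accumulated*.

## Decoding

The classifier is a five-class SVM with Gaussian kernel
`exp(−‖u−v‖²/(2σ²))` and one-vs-one voting (libsvm via e1071). Design
decisions:

* **Folds.** Stratified 30-fold cross-validation: 450 balanced trials give
  30 folds of 15 trials, 3 per class; remainders are dealt round-robin.
  Fold assignment is seeded and deterministic. Reported accuracy is the
  mean per-fold accuracy, which for equal folds equals the pooled
  confusion-matrix trace over the trial count.
* **Kernel width σ.** Cross-validated accuracy is piecewise constant in σ,
  so the "gradient ascent on accuracy" is realized as a finite-difference
  ascent in log σ (step halved when no neighbour improves, stop at
  `max_iter` or step < 10⁻³), run from three log-spaced starts because the
  landscape has flat plateaus that stall a single ascent. The default in
  `cross_validate()` is the cheaper non-leaking heuristic — median pairwise
  feature distance computed on each training split — which is what the
  large simulation runs use; `optimize_sigma()` is the tuner, validated
  against a 30-point log-grid search.
* **C** is fixed at 1 (exposed, never tuned): with the kernel width as the
  tuned length-scale, decoding here is insensitive to the soft-margin cost.
* **Ties** in one-vs-one voting follow libsvm's deterministic internal
  rule (first class in order of appearance).

## The max-statistic null and significance maps

Decoding accuracy is reported per electrode, and the best electrode is then
selected — so "is 30% better than chance?" must be answered against the
distribution of the *best* accuracy under label exchange, not the
single-electrode null. `permutation_null()` therefore: draws a subject
uniformly, shuffles its labels uniformly, reruns the full per-electrode CV
decoding, and records the **max accuracy across the electrode subset**; 100
permutations by default. With 17 electrodes this null centres well above
20% — the max-statistic inflation — which is exactly why thresholding
against it controls the familywise error of the electrode search.

`fit_null_normal()` fits a normal to the ensemble (optionally truncated at
an upper accuracy cutoff, reproducing a body-only fit that excludes the
extreme right tail) and reports a K-S statistic. The plain K-S p-value is
anti-conservative when the parameters are estimated from the same sample;
a Lilliefors-corrected variant sits behind a flag. Note that a K-S p-value
just below 0.05 nominally *rejects* normality — the package reports the
statistic and leaves the interpretation to the user.

Significance is expressed as the one-tailed upper-tail probability of the
fitted normal at the observed accuracy, presented as `log10(1/p)` (p is
floored at the smallest positive double before the logarithm). The
three-sigma threshold `mean + 3·sd` corresponds to p ≈ 0.00135. On the
percentage scale the worked example is `23.81 + 3 × 1.76 = 29.09` — note
that 1.76 must be a standard deviation for this arithmetic to hold, and the
package implements it as such.

`band_time_significance()` assembles the 6-band × 16-window map. With
several subjects the per-cell value is by default the *mean over subjects
of each subject's best-electrode accuracy* (`mean_of_best`), with
`best_of_mean` as the alternative reading; the cell's electrode label is
the electrode with the highest subject-mean accuracy.
`best_window_per_band()` takes the per-band argmax of `log10(1/p)`,
earliest window on ties.

Group comparisons mirror the conventional toolchain: a two-way
fixed-effects ANOVA (signal kind × electrode, subjects as replicates, with
interaction) with Tukey–Kramer studentized-range pairwise comparisons
(`compare_phase_power()`, via `aov`/`TukeyHSD`), and a one-way ANOVA across
bands with equal-variance two-sample t-tests for designated pairs
(`band_accuracy_anova()`). The two-way F statistics are verified against
textbook sums-of-squares formulas in the tests.

Topographies (`topography_map()`) use piecewise-linear barycentric
interpolation on a Delaunay triangulation of the electrode positions
(Bowyer–Watson, implemented in the package and tested against the
empty-circumcircle property), `NA` outside the convex hull. Electrode
coordinates are schematic 2-D projections stored as metadata — topography
needs only the relative layout, and no coordinate set is canonical for
this analysis.

## Numerical and degenerate-input choices

* Serialization is a single-file binary container (JSON header +
  little-endian doubles) with bit-exact round-trip; all invariants are
  re-validated on load and malformed files raise format errors naming the
  offending field.
* `baseline_correct` is idempotent; the post-correction baseline mean is
  zero to 10⁻¹⁰ relative.
* `reject_epochs` with an all-rejecting threshold returns a valid empty
  object with a warning, not an error; a threshold of 0 removes every
  non-flat trial.
* Degenerate nulls (zero spread, fewer than 20 retained values after a
  cutoff) refuse to fit; unfitted nulls refuse to convert accuracies to
  p-values.
* Collinear electrode layouts refuse to triangulate.
* All randomness flows through explicit integer seeds; child seeds are
  derived arithmetically and stay below 2³¹.

## Problem sizes used by the shipped validation

The test-suite simulations run at the data-model scale (450 trials, 500 Hz,
750-sample epochs) with sizes chosen as a deliberate compute budget:
chance-level recovery uses 100 ms feature windows (50 phase samples) over
17 electrodes × 20 seeds with the full 30-fold CV; the phase/power
dissociation uses 5 seeds per coding, the five target electrodes, and
max-statistic nulls of 20 permutations; the null-inflation check uses 210
permutations split over 7 seeds at 10 trials per class. The acceptance
script reruns the chance-level computation from scratch at the same sizes.

## Known limitations

* The Gaussian, stationary background understates real EEG artifact
  structure; the amplitude-threshold `reject_epochs` is a stand-in for
  interactive artifact screening and ICA-based cleaning, which are out of
  scope.
* The normal model of the max-statistic null is an approximation (maxima
  are right-skewed); the truncated-fit option exists precisely because the
  body and the tail of such ensembles differ.
* Per-electrode decoding ignores cross-electrode covariance by design —
  the question is *where* information is, not the best achievable joint
  decoder.
* The growing-window analysis is interpreted as fixed start / growing
  length; if the alternative reading (fixed length, stepped start) is
  wanted, the sliding grid already provides it.
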