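---
title: "Recognising primary tastes from facial sEMG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognising primary tastes from facial sEMG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tastemg)
library(dplyr)
```

## The problem

When a person tastes something, facial muscles and salivary glands react:
the masseter, the depressor anguli oris and the depressor labii inferioris
all receive drive from the facial nerve, and their electrical activity can
be read from the skin with surface electromyography (sEMG). `tastemg`
implements a complete analysis chain for asking whether those signals
carry enough information to tell the six taste classes apart — a no-taste
control plus sour, sweet, bitter, salty and umami — using multichannel
facial sEMG recorded at 1000 Hz on six electrodes (channels 1–2 a
differential pair over the parotid/masseter region, channels 3–6
single-ended).

Because taste-evoked facial sEMG datasets are not publicly deposited, the
package ships a synthetic study generator that reproduces the statistical
structure the analysis relies on. Everything downstream — cleaning,
feature extraction, classification, selection sweeps, the activity map —
is agnostic about whether trials come from the generator or from disk.

## The synthetic study generator

A study is described by a `study_spec()`: subjects, sessions per subject,
and one 12 s trial per taste per session, in an order randomized by the
seed. Each trial is the sum of four components, per channel:

* **Band-shaped muscle activity.** White Gaussian noise is transformed to
  the frequency domain, each bin is scaled by the taste profile's gain
  for the band containing it (13 bands: nine 10 Hz bands from 10–100 Hz,
  four 100 Hz bands from 100–500 Hz), and the result is transformed
  back. This inverse-DFT construction gives exact control of band
  energies, which is what the spectral oracle tests check.
* **Baseline drift.** A random quartic polynomial per trial and channel
  (coefficient SD = `drift_amplitude`, default 5 signal units),
  matching the degree of the detrending stage so that detrending is
  testable by construction.
* **Power-line interference.** A 50 Hz sinusoid with harmonics up to
  450 Hz whose amplitudes decay geometrically (factor 0.5), random phase
  per trial. The differential channels 1–2 receive a quarter of the
  single-ended amplitude (0.5 vs 2 units), reflecting common-mode
  rejection; the spec constructor enforces that ordering.
* **Sensor noise.** White Gaussian noise, SD 0.15 units.

The default taste profiles share a common spectral backbone — gain 1 in
10–100 Hz, where most sEMG energy lives for large circular electrodes
(which low-pass filter the source spatially) — and differ *only* in the
100–400 Hz bands of channels 3, 4 and 6. The contrast magnitudes order
the classes as sour ≫ salty ≈ bitter > sweet ≈ umami > none, with
distinct per-channel patterns inside each tier so that every pair of
classes is separable. The magnitudes are free design parameters: no
quantitative per-muscle amplitudes exist to estimate them from, so they
were fixed once at values that give a realistic ordering and clear class
structure, and are not tuned thereafter.

What the generator deliberately does **not** model: motor-unit action
potential trains, electrode transfer functions, session- or day-level
nonstationarity, fatigue, ECG crosstalk or motion spikes. Real
recordings contain all of these, which is why synthetic classification
accuracies here are far higher than anything achievable on real
subjects; passing the recovery tests shows the pipeline is correct, not
that the task is easy in vivo.

## Cleaning

Trials are first cut into 1 s windows advanced by 0.25 s (`segment_windows()`),
giving 45 windows per 12 s trial; a window is kept only if it fits
entirely inside the trial. All subsequent cleaning operates per window,
because segmentation precedes filtering in the pipeline's contract, and a
1 s span is short enough that drift is locally polynomial.

1. **Detrend** (`remove_trend()`): the least-squares quartic over the
   window's time axis is subtracted per channel.
2. **High-pass** (`highpass_filter()`): a causal fourth-order Butterworth
   at 10 Hz, applied in a single forward pass — a zero-phase
   forward–backward pass would double the effective order and change the
   documented −3.01 dB cutoff response. Start-up transients are tamed by
   step-matched initial conditions: the filter state is initialized as if
   the window's first sample had been held forever.
3. **Adaptive notch** (`adaptive_notch()`): for each multiple of 50 Hz up
   to 450 Hz, the window's amplitude spectrum is tested; a harmonic is
   notched only when its peak exceeds `trigger_ratio` (default 4) times
   the local background. The background is the larger of the two
   one-sided medians over ±10 Hz (the harmonic ±2 Hz excluded): taking
   the max of the sides keeps the detector quiet when a harmonic sits on
   a spectral shelf, while a genuine line towers over both sides.
4. **Rejection** (`reject_sample()`): after notching, any harmonic whose
   line-to-background ratio still exceeds the threshold (default 4)
   flags the window; flagged windows keep their data but are excluded
   from feature extraction. With the default trigger and rejection at
   the same ratio, an untriggered harmonic can never cause rejection.

Two notch design choices deserve explanation. First, the second-order
notch magnitude response is applied zero-phase in the frequency domain
(circular convolution) rather than as a time-domain IIR pass: on a 1 s
window a causal or filtfilt biquad leaves a substantial edge transient
that caps line suppression near 80 %, whereas the circular application
removes a phase-continuous on-bin line essentially completely while
touching only the notch bandwidth. Second, the comb uses a **constant
absolute bandwidth**: `quality_factor` (default 30) is defined at the
fundamental, so every notch is 50/30 ≈ 1.7 Hz wide, and higher harmonics
get proportionally larger Q. A constant-Q comb would widen with
frequency (15 Hz at the 9th harmonic) and measurably bite into
neighbouring spectral bands; with constant bandwidth the full chain
preserves the muscle signal's band energies within 10 % outside ±2 Hz
of the harmonics, which the test suite verifies end to end.

## Features

`extract_features()` computes 21 feature types per channel per window
(126 features on six channels), named `ch<c>_<type>` in channel-major
order:

* 13 **band averages**: the mean one-sided spectrum amplitude over each
  band, `F[n] = (1/w) Σ f(i)` with 10 Hz bands between 10 and 100 Hz
  and 100 Hz bands between 100 and 500 Hz (half-open intervals). The
  index arithmetic requires 1 Hz resolution, i.e. window length equal to
  the sampling rate; anything else errors rather than silently rebins.
* 3 **spectral moments**: frequency centroid FC, root-mean-square
  frequency RMSF and root-variance frequency RVF, the weighted mean,
  root second raw moment and root second central moment of the bin
  frequencies under the amplitude spectrum. They satisfy
  RMSF² = RVF² + FC² exactly.
* 5 **time-domain statistics**: RMS, zero-crossing count (strict sign
  changes; a zero sample never contributes), mean absolute value, and
  kurtosis and skewness standardized with the population (divide-by-L)
  standard deviation; kurtosis is raw (Gaussian ⇒ 3), not excess.

The square roots in RMS, RMSF and RVF follow the feature *names*; the
`literal_equations` flag computes the unrooted second-moment variants
instead for users who want the raw power-style quantities. DFT
magnitudes are used unscaled — every feature is either linear in the
spectrum or a ratio, so any fixed scaling convention is internally
consistent; ours is fixed and documented for reproducibility.

Every feature is checked against an independent direct-summation oracle
(plain loops over the defining sums) to 10⁻⁸ relative error, and the
spectrum itself against an O(L²) DFT.

## Classification and selection sweeps

Windows overlap heavily (0.25 s step on 1 s windows), so neighbouring
windows from one trial are nearly duplicates. Cross-validation therefore
groups at the **session** level (`session_folds()`): sessions are
shuffled by seed and dealt round-robin into 5 folds, and every window
inherits its session's fold. No session ever contributes to both sides
of a split — the decisive protection against leakage optimism.

`taste_rf_cv()` fits a random forest per fold (`ranger`, 500 trees,
√D candidate features per split, single-threaded for determinism) and
reports per-fold accuracies, the row-normalized 6 × 6 confusion matrix of
the pooled predictions, and Gini (impurity-decrease) importances,
normalized per fold to sum to one and averaged across folds. Feature-type
scores aggregate the per-feature importances over channels
(`feature_type_importance()`), with ties broken by type index.

Three sweeps explore model simplification, all reusing the same folds and
seed so that subset results are directly comparable:

* `sweep_feature_types()` — keep the top-NF types for NF = 1…21; the
  NF = 21 point reproduces the full model exactly.
* `sweep_channels()` — evaluate all 63 non-empty channel subsets;
  `sweep_summary()` gives the best and mean accuracy per subset size.
* `sweep_subjects()` — evaluate all non-empty subject subsets (127 for
  seven subjects), drawing session-grouped folds within each pooled
  subset; the grouping rule applies unconditionally.

Forest size is the only computational knob varied between contexts: the
main CV uses the 500-tree default, while sweeps (dozens to hundreds of
fits) use 200 trees, which changes accuracies by far less than the fold
spread.

## The muscle-activity map

For channels 3, 4 and 6 — the single-ended electrodes whose
un-differenced amplitudes reflect raw signal strength over the depressor
anguli oris, depressor labii inferioris and masseter — the activity proxy
S is the sum of the one-sided amplitude spectrum over 100–400 Hz. The
band is taken half-open, `[100, 400)`, so that
`S = 100 × (band_100_200 + band_200_300 + band_300_400)` exactly;
frequencies below 100 Hz are excluded because they carry little class
contrast despite holding most of the energy. `taste_activity()` averages
S per taste and channel (18 values), and `grayscale_map()` maps the table
linearly to integer grayscales with the smallest value at 0 (black) and
the largest at 255 (white), rounding half away from zero; a constant
table maps to all zeros, and the map is order-preserving. Because one can
equally argue for rendering *stronger* activity as *darker*,
`activity_grayscale(..., invert = TRUE)` and the `autoplot()` method
provide that presentation-layer inversion without changing the numeric
rule.

```{r activity-demo}
spec <- study_spec(n_subjects = 1, sessions_per_subject = 2,
                   trial_duration = 2, seed = 42)
feats <- generate_study(spec) |>
  segment_windows() |>
  preprocess_windows() |>
  extract_features()
taste_activity(feats) |> activity_grayscale()
```

## Numerical choices and degenerate inputs

* Segmentation errors on window or step lengths that are not integer
  sample counts; a trial shorter than one window yields an empty window
  list, not an error.
* Detrending requires at least degree + 2 points and is idempotent to
  10⁻⁶ relative.
* Spectral moments error on an all-zero spectrum (the ratios are
  undefined); kurtosis and skewness error on constant windows (σ = 0)
  but only when actually requested, so RMS/ZCR/MAV of a constant window
  still work.
* All randomness flows from explicit integer seeds: trial synthesis
  derives a per-(subject, session, taste) seed from the spec seed, and
  fold shuffles and forests take their own seed, so a `(config, seed)`
  pair reproduces byte-identical outputs.
* Rounding in the grayscale map is half-away-from-zero, clamped to
  [0, 255].

## Problem sizes used in the shipped checks

The validation suite exercises the default study at 1 subject ×
20 sessions (120 trials, ≈5400 windows, 126 features): session-grouped
5-fold CV accuracy must reach 0.90, label permutation must fall within
1/6 ± 0.08, at least two of the four top-ranked feature types must come
from {100–200 Hz, 200–300 Hz, 300–400 Hz, RVF}, and the best 2-channel
subset must lie inside the planted channels {3, 4, 6}. Smaller studies
(2 s trials, 5 sessions) back the unit and property tests, where the
properties under test do not depend on trial length. The
`scripts/acceptance.R` script recomputes all of these quantities from
scratch on a fresh study.

## Known limitations

* The generator's stationary, session-free signal model makes the
  synthetic task considerably easier than real taste recognition;
  absolute accuracies on synthetic data say nothing about accuracies on
  human recordings.
* The notch assumes interference phase-continuous within each 1 s
  window and centred within ±1 Hz of the nominal harmonics; strongly
  off-nominal mains frequency would need a wider search band.
* Only drift and line interference are modelled as artifacts; ECG
  crosstalk and motion spikes are out of scope.
* The channel sweep is exhaustive (2⁶ − 1 subsets) and the subject sweep
  likewise (2⁷ − 1); both scale exponentially and are meant for small
  electrode/subject counts.
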