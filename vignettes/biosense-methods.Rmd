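---
title: "Methods: biosensory session analysis with biosense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biosensory session analysis with biosense}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosense)
```

## What the package models

Sensory-evaluation sessions increasingly pair the *conscious* answers a
panelist types into a tablet form (liking scales, rankings) with
*subconscious* physiological responses of the autonomic nervous system
captured by cameras while the stimulus is experienced: heart rate and blood
pressure inferred from facial video, skin temperature from infrared thermal
images, and facial-expression intensities from expression-analysis software.
`biosense` implements the full analysis chain around such sessions:

1. **session_io** — building/validating the JSON session configuration and
   reading/writing the tab-delimited response and ranking text files the
   tablets produce;
2. **rppg** — green-channel remote photoplethysmography: pulse signal
   extraction, band-pass filtering, spectral heart-rate estimation, and a
   trainable regressor from pulse-shape features to mean heart rate and
   blood pressure;
3. **thermal** — eye-region detection (whole-face fallback) on the visible
   image, visible-to-thermal affine co-registration, and per-frame maximum
   skin temperature;
4. **emotions** — ingestion and windowed summarization of emotion tables
   (eight intensities, valence, arousal, head pose, gaze);
5. **multivariate** — per-sample fusion of all variables, correlation-matrix
   PCA and Euclidean-distance hierarchical clustering of the samples;
6. **synthetic** — seeded generators for every input modality, with ground
   truth, so the chain is testable end to end without human-subject data.

## Session file formats

The configuration document is JSON with a fixed schema (`build_config()` /
`parse_config()`); its field names follow the configurable options of the
form builder: title, three-digit sample codes, per-participant
randomization, question repetition per sample, an optional ranking task,
and an ordered question list with scale kind, levels, conditional jumps,
media attachments and display times. Conditional jumps are validated
eagerly: dangling targets and jump cycles are rejected at build time, so a
deployed configuration cannot dead-end.

Response files are tab-delimited text. An assessment line carries exactly
eight fields — the `Assessment` tag, the assessment kind, the literal token
`Sample`, the sample label, the question kind, the literal token
`Progress`, the numeric value, and a time-of-day stamp with the literal
prefix `Time: `. We treat `Progress` as a per-line token of the dialect
(not a column header) because it recurs on every line of observed output.
A ranking line alternates `Sample <label>` / `Position <n>` pairs.
Timestamps are timezone-naive times of day; the session date lives in the
enclosing file and folder names, so it is file metadata, not a record
field.

Scale ranges are fixed by kind: the 15-unit unstructured line scale spans
[0, 15] (stored at 0.1 resolution), and the continuous face scale spans
[0, 100]. The face-scale range is a design choice: observed outputs span
13–94 on a continuous scale, and [0, 100] is the smallest conventional
range containing them.

Per-participant presentation order is a uniform seeded permutation keyed by
a 32-bit FNV-1a hash of `participant_id|seed`, which makes orders
reproducible across platforms without touching the caller's RNG state. A
balanced crossover design (e.g. Williams squares) is deliberately not
imposed; it can be layered on top by supplying explicit orders.

## Remote photoplethysmography

Blood-volume pulsation modulates skin reflectance most strongly in the
green channel, so the per-frame spatial mean of green intensity over the
face region is the raw pulse signal (`extract_green_signal()`), sampled at
the frame rate (default capture profile: 1640 × 1232 px at 30 fps).
Preprocessing removes the linear trend and applies a zero-phase 4th-order
Butterworth band-pass over **0.7–4.0 Hz** (42–240 beats/min) — the
conventional physiological pulse band; zero-phase (forward–backward)
filtering preserves pulse-shape timing for the morphology features.

Heart rate is 60 × the dominant spectral frequency. The spectrum is a
Welch-averaged periodogram — 10-s Hann-windowed segments, 50 % overlap,
zero-padded to 4096 points — and the peak is refined by parabolic
interpolation of the three bins around the maximum, giving sub-bin
(≪ 1 bpm) resolution on 30-s clips. If the peak does not exceed 5 × the
median in-band power (or the signal is flat), the estimator reports
"no pulse" (`NA` plus a classed warning) rather than a number.
`heart_rate_track()` repeats the estimate over sliding windows (default
15 s window, 5 s step; windows shorter than 10 s are refused) to produce
heart-rate-over-time curves.

The blood-pressure stage is a **trainable regressor, not a clinical
device**: `extract_features()` computes a fixed 11-element vector (dominant
frequency, peak power, half-power bandwidth, RMS, peak-amplitude mean/SD,
inter-beat-interval mean/SD, mean rise and fall times, low-quality flag)
and `fit_vitals_model()` fits a ridge (regularized linear) model per target
(HR, SP, DP) with default penalty `lambda = 1e-3`. Predicted systolic
pressure is floored at diastolic + 1 mmHg so the physiological ordering
always holds. Any calibration shipped or demonstrated here is fit on
synthetic data only and is explicitly non-clinical.

## Thermal pipeline

Detection runs on the visible image of each visible/thermal pair with a
fixed fallback order — eye region, then whole face, then "no subject"
(frame skipped and logged). The shipped reference detector is a classical
heuristic adequate for controlled booth scenes and the synthetic
generator: the face is the bounding box of skin-like pixels (red-dominant,
bright), and the eye band is a dark stripe inside the upper half of the
face *interior* (restricting to the interior stops dark background corners
of the bounding box masquerading as eyes). The detector is a pluggable
function, so a cascade or learned detector can be substituted without
touching the rest of the chain.

Co-registration maps visible coordinates to thermal coordinates with a
2 × 3 affine. The default calibration is the axis-aligned scale implied by
the two image sizes plus a configurable pixel offset (the camera-specific
visible/thermal offset is hardware calibration, exposed as input); with ≥ 3
landmark pairs the affine is the least-squares solution, and the RMS
residual is reported. `max_temperature()` is defined as the maximum over
thermal pixels whose centers map inside the (half-open) region box under
the inverse transform — a definition simple enough to verify against a
brute-force pixel scan, which the tests do on a thousand random rasters.

## Emotion tables

Expression-analysis exports are proprietary, so the package defines its own
CSV dialect (`timestamp`, eight emotion intensities in [0, 1], valence in
[−1, 1], arousal in [0, 1], head pose angles in degrees, gaze) and
validates ranges row by row on ingestion. `summarize_emotions()` takes
component-wise means over fixed windows — permutation-invariant and
range-preserving — which is the form in which emotions enter the fusion.
Gaze is summarized by its window mode and, being categorical in the default
dialect, is excluded from the numeric fusion unless supplied numerically.

## Multivariate fusion, PCA and clustering

`assemble_features()` averages every source across participants within each
sample and joins on the sample label, producing the samples × variables
matrix with the field's conventional symbols (`FS`, `HR`, `SP`, `DP`, `IR`,
`X-Head`, …). Missing sample/source combinations are an error by default;
optional mean imputation is off unless requested.

PCA is computed on **z-scored variables (correlation matrix)** because the
fused columns mix units — liking points, bpm, mmHg, °C; covariance PCA
would be dominated by whichever variable happens to have the largest
numeric spread. Components carry a deterministic sign convention (the
largest-magnitude loading in each component is positive), so biplots and
downstream clustering are stable across runs. Explained variances are
percentages of the total and sum to 100 over the returned components (with
fewer samples than variables the omitted eigenvalues are exactly zero, so
the identity still holds).

"Euclidean clustering" of samples is implemented as agglomerative
hierarchical clustering with **Euclidean distance on the first two
principal-component scores and average linkage** by default. Euclidean is a
distance, not a linkage rule, so the linkage had to be chosen: average
linkage is the least shape-biased of the standard monotone rules; single,
complete and Ward are selectable. Clustering on two components matches the
biplot view in which sample groupings are read.

## The synthetic generators

The generators exist so that every stage has a recovery test against known
ground truth; each returns its truth alongside its artifact and is fully
deterministic per seed (all seeding goes through a saved/restored local RNG).

* **Video**: a parametric skin-tone ellipse with a dark eye band — enough
  for green-channel extraction and the reference detector; photorealism,
  head motion, lighting drift and occlusion are explicit non-goals, so
  passing tests demonstrate correctness of the signal path, not robustness
  to real-world video. The pulse is a sinusoidal green modulation
  (amplitude 2 intensity units by default). The **SNR definition is
  pooled**: `snr_db` is the power ratio of the modulation to the noise
  that survives spatial averaging over the face box, so the stated SNR
  means the same thing at any frame size. Default geometry follows the
  capture profile (1640 × 1232 at 30 fps); recovery sweeps in the tests use
  64 × 48 frames, which leaves the pooled SNR — the quantity that governs
  estimator difficulty — unchanged.
* **Thermal**: pairs every 2 s; three scene classes (eyes visible /
  occluded / no subject) exercise the full fallback chain; the eye region
  holds the hottest pixels at the ground-truth temperature, 0.8 °C above
  the rest of the face. Radiometric noise defaults to 0.02 °C — within the
  sensitivity of modern radiometric cameras, and chosen so that the upward
  bias of a maximum over the few-dozen ROI pixels stays well inside a
  0.1 °C reading tolerance.
* **Sessions**: `scenario_affective_images()` emulates an affective-picture
  session — nine images in three planted valence classes (three positive,
  three neutral, three negative) viewed by 59 participants answering one
  face-scale question; class means 75/50/25 face-scale units (SD 12 across
  participants, per-image offsets SD 4), class-conditional emotion profiles
  (per-image offsets SD 0.02, participant SD 0.08), and mildly
  class-dependent heart rate and skin temperature. `scenario_beer()`
  emulates a nine-style beer tasting with seven liking questions and 30
  consumers. Responses are truncated normals on the scale; each
  participant's ranking is obtained by sorting their own liking draws, so
  rankings are internally consistent; all of these sizes are the package's
  modeled study conditions and are not tuned per test.

## Numerical choices and degenerate inputs

* Filter band edges at exactly the Nyquist frequency are rejected; signals
  shorter than 10 s refuse spectral heart-rate estimation.
* Flat signals yield "no pulse" / zero-amplitude features flagged
  low-quality rather than numbers.
* Constant regression targets produce a constant model with a warning;
  constant columns are dropped from PCA with a warning; a single-row PCA is
  an error.
* Ranking lines must be permutations 1..k; violations name the line.
* Registration transforms are checked for invertibility; a transformed
  region covering no thermal pixel is an error, not a silent `-Inf`.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use sizes chosen to
exercise the estimators well past their operating point while staying
desk-sized: 40 clips of 30 s at 64 × 48 px for the 50–150 bpm sweep at
5 dB pooled SNR; 1000 random 8 × 10 rasters for the brute-force maximum
check; 10-pair ramps for temperature recovery; 9 × 20 matrices for the PCA
oracle; and 100 seeded replicates of the 59-participant image session for
cluster recovery.

## Known limitations

* The rPPG path implements the green-channel method only; chrominance
  methods (CHROM/POS), motion compensation and skin-tone robustness are out
  of scope, and the blood-pressure regressor is a calibration surface, not
  a validated estimator.
* The reference detector is a heuristic for controlled scenes; real
  deployments should plug in a trained detector.
* Proprietary radiometric file formats are not decoded; rasters must be
  exported to CSV/TIFF upstream.
* Facial-expression classification itself is external; only its tabular
  output is modeled.
* Synthetic sessions model between-participant variation as independent
  truncated normals; they do not emulate order effects, fatigue, or
  palate carry-over.
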