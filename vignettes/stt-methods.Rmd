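---
title: "Methods behind sttkit: trace geometry, scoring network, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind sttkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sttkit)
```

## The test and its model

The simple tracing test asks a subject to trace a printed sine wave —
amplitude 35 mm, wavelength 62 mm, four cycles — on a pen tablet, left to
right, at their own pace. The package models the target as
`y(x) = A sin(2π (x − x₀) / λ)` in a coordinate frame with x along the
tracing direction and y upward, both in mm, origin at the wave start on the
centreline. Analysis is restricted to the central three cycles
(`[x₀ + λ/2, x₀ + 7λ/2]` for the default figure): the first and last half
cycles, where subjects start and stop, are excluded.

Four variables summarize a trace over that window, each computed over
recorded samples with no resampling (resampling would silently change sums,
so the sampling rate travels as metadata instead):

1. *Tracing accuracy*: the summed distance from each pen sample to the
   target curve. It is 0 for a perfect trace and grows with deviation.
2. *Pressure-change sum*: `Σ |Δp|` over consecutive samples — the total
   unsteadiness of pen pressure. The clinical description names this
   variable "total sum of pen pressures" but defines it as the total sum of
   *changes* in pen pressure; the definition wins here, and a raw pressure
   sum is deliberately not offered under that name to avoid ambiguity.
3. *Pressure-change max*: `max |Δp|`, dominated by pen lifts (a lift is a
   drop to pressure 0 and back).
4. *Duration*: time from the first to the last sample of the clipped trace,
   in seconds; start and end are determined by the recorded samples, not by
   an examiner.

### Distance to the curve

The clinical description says only "distance between the traced figure and
the task figure". Two readings are implemented. The *vertical* distance
`|y − f(x)|` is what a column-wise comparison of trace and target gives.
The *nearest-point* (Euclidean) distance is the geometric distance to the
curve; it is well defined even where a trace doubles back in x, and never
exceeds the vertical distance. Nearest is the default; neither is claimed
to replicate the original device software, and the mode is a recorded
configuration choice.

Numerically, the nearest distance is found per point by an argmin scan over
a dense curve grid (2048 samples per wavelength) followed by a Newton
refinement of the squared distance, clamped to one grid cell, with a step
tolerance of 10⁻⁶ mm. The scan is restricted to grid points with
`|u − x| ≤ d_vert`, which is exact (any curve point farther than the current
best bound in x alone is farther in distance), and the vertical candidate
`u = x` is always included, so `nearest ≤ vertical` holds exactly. Tests
verify agreement with a brute-force dense-sampling oracle.

### Clipping

Samples are clipped to a window by threshold crossing on recorded x values
(first sample with `x ≥ x_start` through last with `x ≤ x_end`), without
interpolating boundary crossings. This is the simplest defensible reading;
it means per-cycle segments share no samples and their feature sums need
not add exactly to the whole-window value (tests bound the discrepancy by
the boundary increments).

## The scoring network

Scores come from a 3-layer perceptron fixed at 4 inputs, 3 hidden units, 2
outputs: `h = tanh(b₁ + W₁ z)`, `(p₁, p₂) = softmax(b₂ + W₂ h)`. The STT
score is `100 · p(healthy)`, a 0–100 scale where low values indicate
impairment. Design choices where the clinical description is silent:

* **Output activation.** Only the hidden activation (tanh) is documented.
  The published output weights form a near-antisymmetric pair and the
  output is described as a probability, which is consistent with a softmax
  pair trained on cross-entropy; that is what the package implements.
* **Input normalization.** The four variables live on wildly different
  scales (hundreds of mm, tens of thousands of device units, seconds), so
  inputs are z-scored with training-set statistics stored inside the
  parameter object. The constants used by the original model were never
  published; `stt_reference_params()` therefore returns the published
  weights with normalization *unset*, and scoring refuses to run until
  constants are supplied explicitly. Reproductions using the reference
  weights must state their normalization assumption.
* **Class-to-output mapping.** Which output unit meant "healthy" is not
  documented. The mapping is an explicit, serialized field, defaulting to
  `O2 = healthy` (the unit whose published hidden-to-output weights are
  positive for the hidden units that respond negatively to impairment).
* **Training.** Full-batch gradient descent with momentum on cross-entropy,
  weights initialized uniformly in ±0.5 from a seeded RNG. Defaults —
  learning rate 0.1, momentum 0.9, at most 2000 epochs, stopping when the
  epoch-to-epoch loss change drops below 10⁻⁸ — were chosen once for stable
  convergence on cohorts of a few dozen subjects and are recorded in the
  returned object for provenance. The analytic gradient is verified against
  central finite differences in the test suite.

## Diagnostic evaluation

The empirical ROC places candidate thresholds at midpoints between
consecutive distinct scores plus ∓∞ sentinels; midpoints are the common
package convention and match the observation that published cutoffs need
not be observed scores. For the STT score, `lower_is_positive` is the
natural direction (patients score low). The AUC is the trapezoidal area,
which equals the Mann–Whitney pair statistic with ties counted ½ — the test
suite asserts exact rational agreement.

The cutoff minimizes `(1 − sensitivity)² + (1 − specificity)²` — the
squared distance to the ROC's ideal corner — with ties broken by higher
sensitivity, then higher specificity, then the smaller threshold, making
the output deterministic.

AUC confidence intervals default to DeLong (deterministic); a stratified
percentile bootstrap (2000 resamples, mandatory seed) is available. When
the DeLong variance degenerates (AUC exactly 0 or 1), a Wilson-type
interval on the AUC with effective n equal to the smaller class is returned
with a warning, rather than a misleading zero-width interval.

Reliability of per-cycle scores uses the intra-class correlation from the
two-way ANOVA decomposition of the subjects × cycles score matrix. The
default variant is two-way mixed, single measure, consistency — ICC(3,1) —
because cycles are a fixed set of repeated segments of one trace, not a
random sample of raters; the absolute-agreement variant ICC(2,1) is
selectable, and results always label the variant used. Spearman correlation
uses Pearson on average ranks with a t-approximate p value (n − 2 df); the
two-sample comparison defaults to Student's pooled t test ("unpaired
t-test"), with Welch selectable.

Published sensitivities/specificities are reported rounded half-up to 2
decimal places to match clinical presentation; raw precision is retained
in attributes.

## The synthetic cohort generator

`simulate_trace()` emulates the generative features that the four variables
are designed to detect: the pen advances at constant speed sampled at
100 Hz (a typical consumer pen-tablet rate); y follows the target curve
plus Gaussian tracking noise and a sinusoidal tremor with seeded phase;
pressure is Gaussian (0–1023 device scale) clipped at zero, with
Poisson-distributed pen lifts that force pressure to 0 for a fixed interval
(lifts are pressure-0 samples, not gaps, keeping timestamps strictly
increasing and exercising the pressure-change-max pathway exactly as a
detached pen would).

The default profiles encode the clinical contrast: the patient profile has
3× the control's tracking noise (3 vs 1 mm), 4× the tremor amplitude
(1.2 vs 0.3 mm), 2 expected pen lifts per trace (vs none), 2.5× the time
per mm (10 vs 25 mm/s), and a spikier pressure signal (sd 30 vs 8). Each
ratio meets or exceeds 2×, the margin chosen so a default cohort separates
with AUC ≥ 0.9 under training at the study's cohort sizes (10+20 training,
15+18 validation).

Cohorts add subject-level heterogeneity: each subject's deviation, tremor,
lift rate, pressure sd and speed are scaled by lognormal multipliers
(`subject_sd = 0.5` on the log scale). Without this, all subjects of a group
would be statistically identical and any two groups would separate almost
perfectly regardless of effect size; with it, single-variable AUCs land in
the 0.8–1.0 range, qualitatively matching the published ordering in which
tracing accuracy is the strongest single variable and duration the weakest.
Randomness uses one root seed from which two child seeds per subject are
drawn (profile jitter, trace noise), so cohorts are reproducible and
order-independent.

What the simulator does *not* emulate: the true trace-level distributions
of patients (unpublished), correlations between the four variables beyond
those induced by the shared profile, fatigue or learning across the trace,
age effects, and the JOA/GRT covariates. Passing synthetic tests therefore
demonstrates that the pipeline recovers *planted* group structure of
realistic shape and size — not that the package reproduces clinical group
means. For that reason the published mean scores (24.4 vs 84.9), Spearman
correlations with JOA/GRT, and the published ICC of 0.78 are checked only
as orderings on synthetic data, never as values.

## Problem sizes and runtime choices

The test suite and the acceptance script size their simulations to the
study's own cohort dimensions: 10+20 training and 15+18 validation
subjects, 20 replicates for end-to-end recovery, 50 seeded runs for the
training-stability property, 500 random score sets for the AUC identity,
and every set size up to n = 30 for the cutoff-enumeration check. At the
default 100 Hz and 10–25 mm/s these give traces of roughly 1000–2500
samples, and the whole suite runs in about a minute and a half on one CPU.

## Known limitations

* The nearest-distance refinement is specific to sinusoidal targets; other
  figures (straight line, sawtooth) are out of scope.
* The reference weights cannot produce scores without externally supplied
  normalization constants, by design.
* DeLong intervals with fewer than 2 subjects per class, and bootstrap
  intervals on very small classes, are unreliable; the package warns or
  falls back rather than refusing.
* The trace CSV dialect is the package's own (documented, diff-able);
  vendor tablet formats are not parsed.
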