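---
title: "Event-centered segmentation for fall detection: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-centered segmentation for fall detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models behind `fallseg`, the parameters
that matter, the numerical conventions, and the places where a design
had to be chosen among defensible alternatives.

## The pipeline

A fall recorded at the waist follows a three-phase morphology: a
pre-impact (falling) phase in which the acceleration magnitude drops
below the 1 g rest level, an abrupt impact spike when the body meets
the ground, and a rest phase near 1 g.  The pipeline exploits this
structure in five stages: quality control on the acceleration vector
magnitude (AVM), detection of potential fall events, extraction of
event-centered records, multi-window segmentation, and cross-validated
SVM classification of per-window features.

The unit of classification is the *event-centered record*: the ±4 s
tri-axial excerpt around one detected potential fall event.  Every
event, not every source record, contributes one row to the classifier
— a fall record that also triggers on pre-fall activity contributes an
ADL-labeled row too, which is exactly the hard negative such systems
face in practice.

## Tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| detection threshold | g | calibrated | largest grid value detecting all falls minimises ADL alarms |
| calibration grid | g | 0–5, step 0.005 | fine enough to sit just under the weakest fall peak |
| quiet period | s | 2.5 | falls are one-off events; repeated peaks within 2.5 s indicate rhythmic activity |
| extraction margin | s | 4 | bounded by the usable duration of short activity records |
| t1, t2 range | s | 0–4, step 0.5 | window ends cannot exceed the extraction margin |
| t3 (≤ t1), t4 (≤ t2) | s | step 0.25 | finer inner grid sizes the impact window |
| SVM cost C | — | 1 | fixed so the sweep isolates the segmentation effect |
| CV folds k | — | 5 | standard; every record tested once |

## The detector and its edge cases

A sample *i* is a potential fall event iff `AVM[i] > threshold` and
every sample in the window `(i, i + round(2.5 * fs)]` is strictly
below the threshold.  Conventions, chosen once and applied everywhere:

* **Strict inequalities.**  The event needs `AVM > θ`; quiet needs
  `AVM < θ`.  A sample exactly at θ neither triggers nor counts as
  quiet.
* **Runs of crossings.**  Within a run of consecutive above-threshold
  samples only the last can qualify — every earlier one is followed by
  another crossing.
* **Truncated windows count as quiet.**  Fall records typically end in
  rest shortly after the impact; demanding a full quiet window would
  silently discard valid falls.  The corollary is that the *last*
  crossing of any series is always an event, so a walking record whose
  steps defeat the quiet rule everywhere still yields one boundary
  event.  That event carries less than the required 4 s tail margin and
  is dropped at extraction, which restores the intended behaviour
  (sustained walking contributes no classifier rows).
* **Threshold monotonicity does not hold.**  Raising the threshold can
  silence a peak that previously broke another peak's quiet window and
  thereby *create* an event.  The test suite pins a counterexample; the
  properties that do hold (the crossing set shrinks; every event is a
  crossing; the last crossing is an event) are asserted instead.
* **Labeling.**  In fall records, events at or after the index of the
  global AVM maximum (first occurrence on ties) are falls; earlier
  events are ADL.  This presumes the fall impact dominates the record,
  which the generator guarantees for falls preceded by an ADL.
* **Rounding.**  All second→sample conversions use `round(t * fs)`,
  giving symmetric error across sampling rates; indices are 1-based
  with `t0_time_s = (t0_index - 1) / fs`.

Threshold calibration is implemented by interval arithmetic: a sample
at/after the record maximum is a fall event for exactly the open
threshold interval (max of its quiet window, its own AVM); the
calibrated value is the largest grid point inside every record's union
of intervals.  The comparisons mirror the detector's bit for bit, and
the test suite confirms equality with a full-grid brute force.

## The window grid

Half-open boundaries `[start, end)` keep adjacent windows disjoint;
the event sample belongs to the impact window W1 whenever W1 is
non-empty.  The 81 × 81 grid of (t1, t3) × (t2, t4) combinations minus
the all-zero tuple gives 6560 configurations — the all-zero tuple is
the single exclusion because every window is empty there.  Sixteen
tuples (t3 = t4 = 0 with exactly one of t1, t2 positive) leave only a
pre- or post-impact window; the canonical five-class criteria do not
cover them, so they are classified `W2` and `W3` and swept like any
other configuration.

## Features

Eight per-window features, all homogeneous of degree 1 in the axes:
mean, max, min, range and population standard deviation (divisor *N*)
of the AVM; the summed magnitude area `sum(|ax|+|ay|+|az|)`; the mean
absolute difference of consecutive AVM samples (AAMV); and
`sqrt(sum(AVM^2))`.  Two conventions were genuinely open:

* AAMV's sum over consecutive differences has *N* − 1 terms; the
  default divides by *N* − 1 (a true mean), with the divisor-*N*
  variant behind `aamv_divisor = "n"`.
* The root-summed-squares feature applies the square root by default;
  `rms_sqrt = FALSE` gives the plain sum of squares.  Neither variant
  is normalised by *N*, so both grow with window length — features are
  standardized downstream, making this a per-configuration constant.

No orientation features are computed: they would require a known
sensor orientation on the body, which the random per-record
orientation of the generator deliberately denies.

## Classification

An RBF-kernel SVM with C = 1.  Standardization parameters (mean, SD
per feature) are fit on the k − 1 training folds only and applied to
the test fold; the gamma heuristic — 1 / (number of features × pooled
variance of the standardized training features) — is likewise fit on
training data.  Folds are a plain seeded random partition keyed only
by (seed, record ids), so every window configuration is judged on the
identical partition and fold assignment can never leak label or
feature information (stratified splitting is available behind a flag).
Confusion counts are summed over folds before metrics are computed —
equivalent to averaging per-fold Fscores up to fold-size weighting,
and better behaved when a fold lacks one class outcome.  Zero-
denominator metrics are `NA`, never silent zeros.  Per-class maxima
break ties toward the smaller t1 + t2 + t3 + t4, then
lexicographically.

## The synthetic generator

The generator emulates what the pipeline assumes about waist-worn
accelerometry, not human biomechanics.  A record is a magnitude
profile assembled from phases (rest at 1 g, descent ramps, half-cosine
impact pulses, two-harmonic periodic motion, posture bumps), projected
onto a random static unit orientation and given per-axis Gaussian
noise (default SD 0.03 g, small against the 1 g rest level).  With
zero noise a rest phase reads exactly 1 g.  The built-in library
covers: flat falls; falls out of walking; broken falls with a second
impact 0.8 s after the first; falls preceded by a sit-down ADL
(producing the pre-fall false trigger); low-peak slow ADL; impact-like
ADL (sitting down hard at 1.5–3 g, jumping) that settle with small
motion afterwards; and sustained 1.8 Hz walking whose steps recur
faster than the quiet period.  Falls place the primary impact ≥ 4.5 s
from both record ends so the ±4 s extraction is always exercisable; a
`short_tail_frac` flag truncates records 2 s after the impact to
exercise the retention accounting.  All phase durations carry 10%
per-record jitter so no class has a deterministic timing fingerprint,
and impact/descent durations are identical across classes — without
this, a kernel classifier happily keys on pulse width rather than on
anything a segmentation study is about.

The `difficulty` knob (0–1) moves class signal out of the impact
window: it converges the pre-impact dip depths of falls and
impact-like ADL and shrinks the fall amplitude range (2–8 g at
difficulty 0) toward the ADL range, while leaving the pre/post-impact
structure — walking before some falls, rest after falls versus
settling after ADL impacts — untouched.  At difficulty 0 the classes
are linearly separable (disjoint dip depths, far-separated
amplitudes); at difficulty 1 the surviving signal sits mainly in the
pre- and post-impact intervals, the regime in which comparing window
configurations is informative.  Sensor errors are injected
deterministically from the seed: a one-sample 35 g spike (tripping the
30 g rule) and a compression of the whole AVM trace to a 1.05 g
maximum (tripping the 1.1 g fall rule), each flagged in the manifest
so QC fidelity is testable record for record.

What the generator does **not** emulate: realistic elderly-fall
biomechanics, gyroscope/barometer channels, sensor drift or
saturation, and the long-tailed diversity of free-living ADL.  Passing
tests therefore show the pipeline is correct and that the window-
configuration comparison behaves as designed under controlled class
structure — not that any particular accuracy transfers to real
recordings.

## Problem sizes

The shipped study and tests run at desk scale by choice: cohorts of
100 falls + 100 ADL at 100 Hz, the full 6560-configuration grid for
enumeration and classification checks, and a reduced t_max = 2 s
(624-configuration) grid for the cross-validated sweeps, repeated at
three seeds for the directional window-class comparison.  The full
4 s grid sweep is a single `enumerate_configs()` argument away and
scales linearly in configurations.

## Known limitations

* The detector's boundary-event behaviour (last crossing always
  qualifies) is a modelling decision, not a ground truth; streaming
  deployments would buffer instead of truncating.
* Calibration assumes every fall record contains a detectable
  post-maximum event; a cohort violating this returns `NA` rather than
  a threshold.
* Features are sampling-rate dependent (SMA and the root-summed
  squares scale with window sample count); cross-rate pooling relies
  on per-fold standardization.
* The SVM is fixed (C = 1, RBF, heuristic gamma) by design — the
  package isolates segmentation effects and is not a classifier
  benchmark.
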