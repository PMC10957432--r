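---
title: "Processing cardiotocography archives: models, rules and tunables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing cardiotocography archives: models, rules and tunables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgkit)
```

# The processing model

Electronic fetal monitoring produces three signals at 4 Hz — fetal heart
rate (FHR, bpm), uterine pressure (UP, uncalibrated 0–100), and maternal
heart rate (MHR, bpm) — but never cleanly. Sensors disconnect, leaving
*gaps*; the monitor stores a heart rate of 0 when it cannot estimate one
(*dropouts*); interrupted monitor–server links resend packets, producing
*duplicate timestamps*; and the same physiological quantity moves between
sensors during labor (external ultrasound to fetal scalp ECG; TOCO belt
to intrauterine catheter). `ctgkit` models all of this explicitly and
carries each tracing through five stages: parse → combine → repair →
patterns → features, with an outcome classifier on the clinical side.

All internal times are signed seconds relative to birth: birth is 0 and
everything before birth is negative. Input files carry non-negative
milliseconds-before-birth; conversion happens once at parse time so every
later stage shares one unambiguous axis. Floating-point time comparisons
use an absolute tolerance of `delta/100` (2.5 ms at 4 Hz).

## The segmented-signal container

A `seg_signal` stores the concatenated samples of all contiguous segments
plus segment start times and lengths. Onset pointers (the index of each
segment's first sample in the concatenated vector) are 1-based, matching
both R convention and the way such structures are conventionally printed;
`onset_offsets()` exposes the 0-based equivalents. A *gap* is any
inter-sample step greater than one sampling increment — there is no
minimum gap duration. Dropout samples (FHR = 0) are *stored samples*, not
gaps; they are converted to gaps only by the repair stage, so that the
raw record remains a faithful image of what the monitor wrote.

Sensor/monitor provenance is tracked **per sample**, not per segment.
The alternative — splitting segments at sensor switches — would create
abutting segments with zero gap between them, contradicting the rule that
segments are separated by at least one missing sample slot. Per-segment
labels (`seg_sensors()`) are derived as the label of each segment's first
sample.

## Parsing rules

*Identifier normalization.* Raw maternal record numbers arrive as 7, 8 or
12 digits: 12-digit values carry the "1100" institutional prefix,
8-digit values lack it, 7-digit values additionally lost a leading zero.
`normalize_mrn()` pads and prefixes so every accepted identifier is
exactly 12 digits; values with nonnumeric characters are rejected, as are
lengths below 7 or above 12. Lengths 9–11 match no known form and are
rejected as length errors — a deliberate choice, since silently padding
them would fabricate identifiers.

*Duplicate timestamps.* Within one signal (measurement × sensor ×
monitor) at one monitor timestamp: if no reading is valid the sample is
dropped; one valid reading is kept; among several valid readings the one
from the highest file row wins, on the rationale that a resent packet is
likely a corrected value. "Valid" means present, numeric and physically
plausible: 0–300 bpm for heart rates (0 being the dropout marker, which
is deliberately *valid*), 0–100 for uterine pressure. The source does not
define validity; these ranges come from the monitor semantics.

*Retention window.* Samples more than 72 h before birth are discarded; a
tracing with nothing inside the window is excluded
(`outside_window_prior`). A sample exactly at −72 h is retained ("earlier
than 72 hours" is strict).

## Sensor combination

Where channels overlap, the clinically more accurate sensor wins
pointwise: FECG over external ultrasound for FHR, the internal catheter
over TOCO for UP. Where two same-precedence channels overlap (external US
on both HR1 and HR2), HR2 wins — HR2 was the usual receptacle. The merge
never invents samples: every output sample exists, with its value and
time, in some input channel, and combination is idempotent. Per-sample
provenance lets downstream code determine the sensor in use at any
instant.

Duplicate tracing files linked to one infant resolve as: byte-identical
content → keep the lexicographically lowest GUID, mark the rest
duplicates (no principled choice exists; lexicographic order is a
convention that at least makes the choice deterministic); distinct
content overlapping in time → all "special", set aside; more than one
distinct non-overlapping file → all excluded.

## Repair

The only externally fixed repair rule is the interpolation bound: gaps
strictly shorter than 15 s are bridged linearly between the flanking
samples (a 3.5 s gap between 120 and 134 bpm receives 14 samples on the
line, the first at 120 + 14/15 bpm). Gaps of exactly 15 s stay. Boundary
gaps have no flank and are never interpolated. Original sample values are
never modified.

The uninterpretability heuristics stand in for a proprietary repair stage
whose internals are not published; they are therefore this package's own
documented, configurable rules (`repair_config()`):

| parameter | default | meaning |
|---|---|---|
| `max_interp_gap` | 15 s | strict upper bound for gap bridging |
| `mhr_coincidence_tol` | 5 bpm | FHR–MHR agreement tolerance |
| `mhr_coincidence_min` | 60 s | minimum continuous agreement flagged as maternal capture |
| `noise_jump` | 25 bpm | sample-to-sample change counted as impulse artifact (≥3 within 10 s) |
| `physiologic_range` | 50–240 bpm | plausible FHR range |

NOI intervals are recorded as events rather than deleted, so feature
extraction can exclude exactly those samples. UP is never interpolated:
the stated repair applies to FHR only, and fabricating uterine pressure
would corrupt contraction areas. Dropout-only gaps and transmission gaps
are treated identically by interpolation; the source does not distinguish
them, and the flanking-sample geometry is the same.

# Pattern detection

The published event definitions (baseline, acceleration, deceleration,
contraction) come from bedside practice; the detector that produced them
in the original workflow is a neural network whose internals are not
reproducible. `ctgkit` substitutes deterministic rules with every numeric
parameter exposed in `pattern_config()`:

- **Baseline**: a 10-minute windowed mean that excludes candidate
  excursion samples (deviating more than 15 bpm), iterated at most 5
  times from a running-median start. Spans shorter than 2 min of
  contiguous interpretable data get no baseline and become RIN.
- **ACC/DEC**: a maximal run outside the ±10 bpm baseline band qualifies
  iff its peak excursion exceeds 15 bpm *strictly* and its duration
  exceeds 15 s *strictly*. Height is the peak |deviation|; area is
  Σ|deviation|·Δ/60 in beats. Strictness matters: a +15.0 bpm plateau of
  any duration is not an event, nor is a −20 bpm dip of exactly 15.0 s.
- **Subtypes**: ≥120 s → prolonged; onset-to-nadir < 30 s → variable
  (the 30 s abrupt/gradual boundary is the standard clinical convention,
  since the source says only "abrupt" vs "gradual"); gradual and paired
  with an overlapping contraction → early if the nadir is within 15 s of
  (or before) the contraction peak, late if more than 15 s after;
  gradual and unpaired → variable. The 15 s "coincide" tolerance is a
  choice — the source's wording is verbal.
- **Contractions**: a 30 s moving average must rise ≥15 units above the
  resting tone (running 10-minute 10th percentile) for ≥30 s. Height and
  area are measured on the *raw* signal against resting tone, because
  smoothing attenuates a 70 s bell's peak by ~28 % and would corrupt the
  reported amplitude.
- **RIN** is defined here as interpretable FHR time not covered by
  BAS/ACC/DEC — the source names the category but never defines it; this
  definition is flagged as a convention. BAS, ACC, DEC and RIN partition
  the interpretable timeline by construction.

# Feature extraction

Epochs tile backwards from birth in non-overlapping 20-minute blocks.
NOI samples are discarded; an epoch is retained iff at least 3840 of its
4800 samples remain (80 %), with the boundary inclusive at 3840.

The FHR is decomposed by FFT into a slow-trend component (|f| ≤ 30 mHz)
and a variability component (everything else); every bin goes to exactly
one component, so the two reconstruct the input to numerical precision.
Samples removed as NOI leave the remaining epoch samples concatenated for
time-domain features while keeping their true timestamps for the
Lomb-Scargle estimates — that estimator's stated advantage is robustness
to gaps, so it gets the honest time axis, whereas FFT decomposition needs
a contiguous series (a documented approximation).

Which feature is computed on which component and event type follows a
cell mask (`default_ctg_feature_mask()`): mean/SD on all six cells; slope
only on the BAS slow component; height/area on the ACC/DEC slow
components (relative to the mean BAS slow level); and the full
variability battery — PRSA AC/DC/DR, LF/MF/HF band powers and LF/(MF+HF),
ApEn/SampEn at m = 2 and r ∈ {0.1, 0.2, 0.3}·SD, Hurst, Lyapunov,
correlation dimension, STV/LTI/Delta/II — on the high-frequency
components of BAS, ACC and DEC. The printed form of this mask in the
source material is typographically corrupted; the mask here is the
coherent reading and is config-overridable, so a different reading costs
one argument. Similarly, whether the entropy/complexity features use the
high-band component (as here) or raw per-event samples is implied rather
than stated; the column layout of the source table supports the high-band
reading.

Numerical notes, by feature:

- **PRSA** (T = 2.5 s, L = 25 s): anchors compare the mean of the T
  window after each point against the T window before; the capacity is
  the Haar quantifier at scale T on the anchor-aligned average. DR =
  DC − AC, the fetal-PRSA literature convention (no formula is printed in
  the source). Anchors require full ±L windows.
- **Lomb-Scargle**: classical normalized periodogram, evaluated on a
  Rayleigh-resolution grid and integrated per band, normalized by signal
  variance. No R package for this is available in the target
  environment, so the estimator is implemented here and verified by
  spectral-concentration properties on planted sinusoids with deleted
  samples.
- **ApEn/SampEn**: textbook definitions (Chebyshev distance; ApEn counts
  self-matches, SampEn does not), with the counting kernel in C++ since
  it is O(n²) on 4800-sample epochs. A constant signal is defined as
  perfectly regular (both 0, flagged degenerate); SampEn with zero
  template matches is NA (invalid), not infinite.
- **Hurst**: rescaled-range over dyadic window sizes from 16, slope of
  log R/S vs log window. Classic R/S carries a known small-sample upward
  bias (~0.54 at n = 4096 for white noise); the white-noise check uses a
  ±0.1 band around 0.5, which the biased estimator meets.
- **LTI** has no printed formula; it is implemented as the interquartile
  range of the moduli √(s_j² + s_{j+1}²) of consecutive 2.5 s grid
  samples (the de Haan convention). This is an open interpretation.
- **Lyapunov / correlation dimension**: embedding (2, 1); nearest-
  neighbor divergence slope (Rosenstein) and Grassberger–Procaccia
  correlation-sum slope respectively, with deterministic thinning to
  bound the pairwise computations. Both are deterministic given the
  input.
- **Transitions**: consecutive FHR events separated by more than 30 s
  (long RIN spans or gaps) are not adjacent; shorter separations do not
  break adjacency. Deceleration subtype frequencies group as late /
  abrupt (= variable) / others (= early + prolonged).
- **Cumulative dwell** is computed for all five event types from
  monitoring start to epoch start; report-time selection of a subset is a
  config concern, since the printed selection table is corrupted in the
  source.

# Outcome classification

Acidosis: lowest-pH cord gas (arterial or venous) with pH < 7.0 or base
deficit ≥ 10 mmol/L, or first infant gas before 2 h of age with BD ≥ 10.
The eight study groups are evaluated in fixed precedence — death under
6 h; perinatal HIE (acidosis AND encephalopathy score > 0 AND ≥1 of
therapeutic hypothermia / abnormal exam ≥6 h / seizures in first 24 h);
distant HIE (imaging pattern, not meeting perinatal HIE); acidosis
without HIE (score = 0 and none of the three); then the healthy vs
intervention split within the no-gas and with-gas branches. The
precedence order is inferred from the decision flow the definitions
imply; it is visible in code and each record's evidence trail logs the
path taken.

One honest gap: an acidotic infant with an abnormal encephalopathy score
but *none* of the three confirmatory criteria satisfies neither the HIE
nor the acidosis-without-HIE definitions. Such records are returned as
`UNCLASSIFIED` with a reason rather than silently binned. Likewise the
"healthy, no acidosis" gas condition is logically looser than the
complement of acidosis; the classifier uses NOT-acidotic and the evidence
trail preserves the gas readings for audit.

HIE severity: moderate-severe iff the worst 1–6 h exam shows ≥3 abnormal
items or there were seizures; otherwise mild.

# The synthetic generator

`simulate_tracing()` states a plausible monitored labor rather than
fitting one: 140 bpm baseline, AR(1) band-limited variability (SD
2.5 bpm, φ = 0.9 — rich enough to exercise the entropy and Hurst
orderings), raised-cosine accelerations (default 20 bpm × 40 s),
piecewise-linear decelerations with controllable onset-to-nadir
(default 30 bpm × 80 s), raised-cosine contractions (height 40, width
70 s, 2 per 10 min) over a resting tone of 10, MHR near 80 bpm, and the
artifact repertoire: scheduled transmission gaps, zero dropout runs
(1 % of samples), duplicate timestamps with corrupted earlier copies
(0.5 %), an external→FECG and TOCO→internal sensor switch at 70 % of the
tracing with a 60 s dual-reporting overlap, and maternal-capture
episodes. Output is deterministic given the seed, in both the tall
per-sample format and the legacy 240-sample one-minute format.

What the generator does **not** emulate: real HIE physiology, baroreflex
coupling between contractions and decelerations, diurnal or medication
effects, or monitor-specific filtering. A green planted-event test
therefore establishes that the detectors implement their stated rules —
not that they would reproduce a clinical expert's annotations.

`simulate_cohort()` draws infant records that satisfy each target group's
definition with margins away from every decision boundary (e.g. cord pH
sampled away from 7.00), so classifier round-trip failures indicate
logic errors, not boundary ties. A boundary-stress mode plants exact
pH = 7.00 / BD = 10.0 cases, flagged in the truth table.

# Persistence

The catalog is a directory of RFC 4180 CSV tables (status, per-signal and
per-segment statistics, events, per-epoch features, processing log,
domain starts) with upsert semantics — re-running a stage replaces a
tracing's rows rather than duplicating them. A single-file SQL store was
the original design, but no SQL driver is available in the target R
environment; the CSV tables keep the same relational shape and load into
any SQL engine unchanged. Labor-onset tables are named in the schema but
their population method is undescribed, so they are out of scope.

# Known limitations

- The pattern detectors are rule-based stand-ins; their thresholds are
  faithful to the printed definitions but the original detector was
  learned, so event boundaries on noisy real data will differ.
- FFT band decomposition treats concatenated post-NOI samples as
  contiguous; only the Lomb-Scargle features use true timestamps.
- The R/S Hurst estimator carries its classic small-sample bias.
- Baseline "variability" (the BAS attribute) is the detrended
  peak-to-peak range, one of several defensible readings of the
  definition.
- The 240-sample legacy writer/reader assumes minute-aligned records, the
  only layout the format description defines.
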