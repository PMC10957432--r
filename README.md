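# ctgkit

Tools for turning raw electronic fetal monitoring (EFM / cardiotocography)
archives into analysis-ready signals, clinically meaningful patterns,
per-epoch feature batteries, and objectively defined perinatal outcome
labels.

## Who this is for

Research groups building large EFM databases face the same chain of
problems: tracings arrive as per-sample dumps keyed by maternal record
numbers that need normalization; the same physiological measurement is
recorded by different sensors at different times (external ultrasound vs
fetal scalp ECG for fetal heart rate, TOCO vs intrauterine catheter for
uterine activity); signals are riddled with transmission gaps, zero-valued
dropouts and duplicated timestamps; and outcome labels such as
hypoxic-ischemic encephalopathy (HIE) must be assigned from blood gases
and neurologic exams by reproducible rules rather than chart impressions.
`ctgkit` implements that chain end to end for 4 Hz fetal heart rate (FHR),
uterine pressure (UP/UA) and maternal heart rate (MHR) signals.

## What it does

- **Segmented signals.** A `seg_signal` stores a gappy signal as
  concatenated samples plus per-segment start times, lengths and 1-based
  onset pointers, with per-sample sensor/monitor provenance. Algebra:
  `find_gaps()`, `to_dense()`/`from_dense()`, `sig_intersect()`,
  `sig_concat()`.
- **Ingestion.** `parse_tracing_csv()` reads tall per-sample files
  (times as milliseconds before birth), resolves duplicate timestamps
  (highest row wins — it is likely a corrected value), and groups
  channels by measurement x sensor x monitor. `normalize_mrn()` applies
  the 7/8/12-digit identifier rules; `apply_birth_window()` enforces the
  72-hour pre-birth retention window; `read_wide_tracing()` converts the
  legacy one-minute 240-sample-per-record format.
- **Combination and repair.** `combine_sensors()` merges channels with
  clinical precedence (FECG > external US; internal catheter > TOCO);
  `repair_record()` turns dropouts into gaps, bridges gaps strictly
  shorter than 15 s by linear interpolation, and flags uninterpretable
  (NOI) spans: maternal-heart-rate capture, impulse noise, out-of-range
  values.
- **Patterns.** `detect_patterns()` partitions the interpretable FHR
  timeline into baseline (BAS), acceleration (ACC), deceleration (DEC)
  and residual (RIN) events using the clinical thresholds — excursions
  of *more than* 15 bpm lasting *more than* 15 s — plus uterine
  contractions (CON) and deceleration subtypes
  (variable/early/late/prolonged).
- **Features.** `extract_features()` computes, per 20-minute epoch
  (retained only when at least 3840 of 4800 samples are interpretable):
  dwell times, transition counts, contraction rate per 10 minutes,
  deceleration subtype frequencies; and a variability battery on the
  0–30 mHz and 30 mHz–2 Hz spectral components by event type —
  phase-rectified signal averaging (AC/DC and deceleration reserve
  DR = DC − AC, with T = 2.5 s, L = 25 s), Lomb-Scargle band powers
  (LF 30–150 mHz, MF 150–500 mHz, HF 0.5–1 Hz, and LF/(MF+HF)),
  ApEn/SampEn (m = 2, r ∈ {0.1, 0.2, 0.3}·SD), Hurst exponent (rescaled
  range), Lyapunov exponent and correlation dimension (embedding 2,
  delay 1), and the classical STV/LTI/Delta/Interval-index battery on
  the 2.5 s grid.
- **Outcomes.** `classify_study_group()` assigns each infant to one of
  eight mutually exclusive groups (perinatal HIE, acidosis without HIE,
  healthy/intervention with and without blood gases, distant HIE, death
  under 6 h) from cord/infant gases (acidosis: pH < 7.0 or base deficit
  ≥ 10 mmol/L), the six-item neurologic exam, and resuscitation/NICU
  flags; `hie_severity()` grades HIE as mild vs moderate-severe.
- **Synthesis and persistence.** `simulate_tracing()` /
  `simulate_cohort()` generate ground-truth fixtures with planted
  physiology and artifacts; `catalog_open()` / `write_catalog()`
  maintain a CSV-backed relational store (status, signal/segment stats,
  events, per-epoch features, coverage).

## Worked example

```r
library(ctgkit)

cfg <- sim_config(seed = 42, duration_h = 2)   # a simulated 2 h labor
csv <- tempfile(fileext = ".csv")
sim <- simulate_tracing(cfg, csv)
res <- process_tracing(csv)

res$repaired
#> <efm_record> SIM00000042 (stage: repaired)
#>   FHR                          1 seg, 28800 samples
#>   UA                           1 seg, 28800 samples
#>   MHR                          1 seg, 28800 samples

table(res$events$type)
#> ACC BAS CON DEC RIN
#>   3  29  24   4  21

res$epochs[, c("epoch_index", "n_interpretable", "retained")]
#>   epoch_index n_interpretable retained
#> 1           5            4800     TRUE
#> ...
#> 6           0            4800     TRUE
```

All six 20-minute epochs are retained (dropouts were bridged by repair,
so every epoch keeps its full 4800 samples). The 24 contractions over
2 h give the expected rate of 2 per 10 minutes; the four planted
decelerations are all recovered. Per-epoch features follow the
`<feature>__<event>__<band>` naming:

```r
f <- res$features
round(f[f$epoch_index == 0,
        c("dwell_BAS", "dwell_DEC", "con_rate_per10min",
          "STV__BAS__high", "SampEn_0.2__BAS__high")], 3)
#>   dwell_BAS dwell_DEC con_rate_per10min STV__BAS__high SampEn_0.2__BAS__high
#> 6   1180.75         0                 2          2.293                  1.47
```

In the final epoch the signal dwells at baseline for 1180.75 of 1200 s
(the rest is sub-threshold excursion time), and the short-term
variability of the baseline's high-frequency component is about 2.3 bpm
— consistent with the simulated variability amplitude.

Outcome classification on a simulated cohort:

```r
cohort <- simulate_cohort(6, seed = 42)
classify_cohort(cohort$records)[, c("infant_id", "group")]
#>   infant_id                    group
#> 1 INF000001            PERINATAL_HIE
#> 2 INF000002            PERINATAL_HIE
#> 3 INF000003      HEALTHY_NO_ACIDOSIS
#> 4 INF000004           DEATH_UNDER_6H
#> 5 INF000005              DISTANT_HIE
#> 6 INF000006 INTERVENTION_NO_ACIDOSIS
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's end-to-end computation from
scratch — simulating a labor tracing, pushing it through parsing, sensor
combination, repair, pattern detection and feature extraction, and
classifying a simulated cohort — and writes its JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Command line

A thin CLI over the same functions lives at `inst/cli/ctgkit.R`
(subcommands `simulate`, `ingest`, `pipeline`, `classify`; stages are
restartable through the `--db` CSV catalog).

## Documentation

The methods vignette (`vignettes/ctg-processing.Rmd`) describes the
processing model, every tunable threshold and its default, what the
synthetic generator does and does not emulate, and known limitations.
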