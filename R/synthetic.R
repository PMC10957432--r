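#' Simulation configuration for synthetic tracings
#'
#' The generator states a plausible monitored labor: a 4 Hz fetal heart
#' rate around a 140 bpm baseline with AR(1) band-limited variability,
#' scheduled accelerations (raised-cosine bumps), decelerations
#' (piecewise-linear, with a controllable onset-to-nadir time), uterine
#' contractions (raised-cosine bells over a resting tone of 10), a
#' maternal heart rate near 80 bpm, and the artifacts the pipeline must
#' survive: transmission gaps, zero-valued dropouts, duplicate
#' timestamps, sensor switches (external ultrasound to fetal scalp ECG,
#' TOCO to intrauterine catheter) and maternal-heart-rate capture
#' episodes.
#'
#' Event schedules are data.frames; pass zero-row frames to disable a
#' feature, or `NULL` to use an automatically generated schedule.
#'
#' @param seed integer RNG seed; the simulation is deterministic given
#'   the seed.
#' @param duration_h tracing length in hours (default 4).
#' @param delta sampling increment, seconds.
#' @param baseline_bpm FHR baseline level (default 140).
#' @param drift_bpm_per_h linear baseline drift (default 0).
#' @param variability_bpm standard deviation of the AR(1) variability
#'   component (default 2.5; 0 for noise-free planted-truth tracings).
#' @param ar_phi AR(1) coefficient of the variability noise (0.9).
#' @param accels data.frame `time_s` (event start, seconds before birth,
#'   negative), `height`, `duration`.
#' @param decels data.frame `time_s`, `depth`, `duration`,
#'   `onset_to_nadir`.
#' @param contractions data.frame `time_s`, `height`, `width`.
#' @param con_rate_per_10min automatic contraction rate when
#'   `contractions` is `NULL` (default 2).
#' @param up_resting uterine resting tone, uncalibrated units (10).
#' @param mhr_bpm maternal heart rate level (default 80).
#' @param gaps data.frame `start_s`, `duration_s` of transmission gaps.
#' @param dropout_rate expected fraction of FHR samples zeroed in short
#'   runs (default 0.01).
#' @param duplicate_rate expected fraction of rows duplicated with a
#'   corrupted earlier copy (default 0.005).
#' @param sensor_switch_frac position (fraction of the tracing) where
#'   FHR switches from external ultrasound to FECG and UP from TOCO to
#'   the internal catheter; `NA` disables switching (default 0.7).
#' @param switch_overlap_s overlap (s) during which both sensors report,
#'   exercising combination precedence (default 60).
#' @param mhr_capture data.frame `start_s`, `duration_s` of episodes
#'   where the FHR channel records the maternal heart rate.
#' @param guid tracing identifier (default derived from the seed).
#' @param monitor monitor label stamped on all rows.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, duration_h = 4, delta = 0.25,
                       baseline_bpm = 140, drift_bpm_per_h = 0,
                       variability_bpm = 2.5, ar_phi = 0.9,
                       accels = NULL, decels = NULL, contractions = NULL,
                       con_rate_per_10min = 2, up_resting = 10,
                       mhr_bpm = 80,
                       gaps = data.frame(start_s = numeric(0),
                                         duration_s = numeric(0)),
                       dropout_rate = 0.01, duplicate_rate = 0.005,
                       sensor_switch_frac = 0.7, switch_overlap_s = 60,
                       mhr_capture = data.frame(start_s = numeric(0),
                                                duration_s = numeric(0)),
                       guid = sprintf("SIM%08d", seed),
                       monitor = "Coro 250") {
  stopifnot(duration_h > 0, delta > 0, dropout_rate >= 0,
            duplicate_rate >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Raised-cosine bump of unit height on [0, width].
raised_cosine <- function(u) 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))

# Piecewise-linear deceleration shape: 0 -> -1 over the onset fraction,
# then back to 0.
dec_shape <- function(u, onset_frac) {
  ifelse(u <= 0 | u >= 1, 0,
         ifelse(u <= onset_frac, -u / onset_frac,
                -(1 - u) / (1 - onset_frac)))
}

default_accel_schedule <- function(duration_s) {
  k <- max(1L, floor(duration_s / 1800))
  data.frame(time_s = -duration_s + (seq_len(k) - 0.25) * 1800,
             height = 20, duration = 40)
}

default_decel_schedule <- function(duration_s) {
  k <- max(1L, floor(duration_s / 1800))
  data.frame(time_s = -duration_s + (seq_len(k) - 0.75) * 1800,
             depth = 30, duration = 80, onset_to_nadir = 50)
}

default_con_schedule <- function(duration_s, rate_per_10min) {
  if (rate_per_10min <= 0)
    return(data.frame(time_s = numeric(0), height = numeric(0),
                      width = numeric(0)))
  spacing <- 600 / rate_per_10min
  starts <- seq(-duration_s + spacing / 2, -90, by = spacing)
  data.frame(time_s = starts, height = 40, width = 70)
}

#' Simulate one tracing with planted ground truth
#'
#' Generates the tall per-sample rows (monitor clock times as
#' milliseconds before birth) for the fetal heart rate, uterine pressure
#' and maternal heart rate channels, together with a ground-truth log of
#' every planted acceleration, deceleration, contraction, gap and
#' artifact episode.  Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param path optional path; when given, the tall CSV is written there.
#' @return a list: `rows` (data.table in tall format), `truth` (list of
#'   data.frames `events`, `gaps`, `mhr_capture`, `dropouts`), `guid`,
#'   and `path` (if written).
#' @export
simulate_tracing <- function(cfg = sim_config(), path = NULL) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(cfg$seed)

  delta <- cfg$delta
  duration_s <- cfg$duration_h * 3600
  n <- round(duration_s / delta)
  tt <- -duration_s + (seq_len(n) - 1L) * delta   # last sample just before 0

  accels <- if (is.null(cfg$accels)) default_accel_schedule(duration_s)
    else cfg$accels
  decels <- if (is.null(cfg$decels)) default_decel_schedule(duration_s)
    else cfg$decels
  cons <- if (is.null(cfg$contractions))
    default_con_schedule(duration_s, cfg$con_rate_per_10min)
    else cfg$contractions
  # planted events of one type must not overlap each other
  chk_self <- function(sch, width_col) {
    if (nrow(sch) < 2L) return(invisible())
    o <- order(sch$time_s)
    s <- sch$time_s[o]; e <- s + sch[[width_col]][o]
    if (any(s[-1] < e[-nrow(sch)]))
      stop("infeasible schedule: overlapping planted events of one type")
  }
  chk_self(accels, "duration")
  chk_self(decels, "duration")
  chk_self(cons, "width")

  # ideal FHR
  drift <- cfg$drift_bpm_per_h * (tt - tt[1]) / 3600
  noise <- if (cfg$variability_bpm > 0) {
    e <- rnorm(n)
    z <- as.numeric(stats::filter(e, cfg$ar_phi, method = "recursive"))
    z * cfg$variability_bpm / sd(z)
  } else rep(0, n)
  fhr <- cfg$baseline_bpm + drift + noise
  for (k in seq_len(nrow(accels)))
    fhr <- fhr + accels$height[k] *
      raised_cosine((tt - accels$time_s[k]) / accels$duration[k]) *
      (tt >= accels$time_s[k] & tt < accels$time_s[k] + accels$duration[k])
  for (k in seq_len(nrow(decels)))
    fhr <- fhr + decels$depth[k] *
      dec_shape((tt - decels$time_s[k]) / decels$duration[k],
                decels$onset_to_nadir[k] / decels$duration[k])

  # uterine pressure
  up <- rep(cfg$up_resting, n)
  if (cfg$variability_bpm > 0) up <- up + abs(rnorm(n, 0, 1))
  for (k in seq_len(nrow(cons)))
    up <- up + cons$height[k] *
      raised_cosine((tt - cons$time_s[k]) / cons$width[k]) *
      (tt >= cons$time_s[k] & tt < cons$time_s[k] + cons$width[k])
  up <- pmin(pmax(up, 0), 100)

  # maternal heart rate
  mhr <- cfg$mhr_bpm + (if (cfg$variability_bpm > 0) rnorm(n, 0, 1)
                        else 0)

  # maternal capture: FHR records MHR during the episode
  mc <- cfg$mhr_capture
  for (k in seq_len(nrow(mc))) {
    sel <- tt >= mc$start_s[k] & tt < mc$start_s[k] + mc$duration_s[k]
    fhr[sel] <- mhr[sel]
  }

  # dropouts: short runs of zeros
  drop_idx <- integer(0)
  if (cfg$dropout_rate > 0) {
    n_runs <- rbinom(1, n, cfg$dropout_rate / 4)
    if (n_runs > 0) {
      starts <- sort(sample.int(n - 10L, n_runs))
      for (s in starts) {
        len <- sample(2:8, 1)
        drop_idx <- union(drop_idx, s:(min(s + len - 1L, n)))
      }
      fhr[drop_idx] <- 0
    }
  }

  # transmission gaps: remove samples from every channel
  keep <- rep(TRUE, n)
  gp <- cfg$gaps
  for (k in seq_len(nrow(gp)))
    keep <- keep & !(tt >= gp$start_s[k] &
                       tt < gp$start_s[k] + gp$duration_s[k])

  # sensor switches
  fhr_sensor <- rep("external", n)
  up_sensor <- rep("TOCO", n)
  if (!is.na(cfg$sensor_switch_frac)) {
    t_sw <- -duration_s * (1 - cfg$sensor_switch_frac)
    fhr_sensor[tt >= t_sw] <- "FECG"
    up_sensor[tt >= t_sw] <- "Internal"
  }

  ms <- function(t) round(-t * 1000)
  mk_rows <- function(vals, meas, sensor, sel) {
    data.table::data.table(
      tracing_guid = cfg$guid, trace_dt = ms(tt[sel]),
      recorded_dt = ms(tt[sel]), measurement = meas,
      sensor = sensor[sel], monitor = cfg$monitor,
      reading = round(vals[sel], 2))
  }
  sel_fhr <- keep
  rows <- list(mk_rows(fhr, "HR2", fhr_sensor, sel_fhr))
  # during the switch overlap, the outgoing external sensor also reports
  if (!is.na(cfg$sensor_switch_frac) && cfg$switch_overlap_s > 0) {
    t_sw <- -duration_s * (1 - cfg$sensor_switch_frac)
    ov <- keep & tt >= t_sw & tt < t_sw + cfg$switch_overlap_s
    if (any(ov))
      rows <- c(rows, list(mk_rows(fhr + 1, "HR2",
                                   rep("external", n), ov)))
  }
  rows <- c(rows, list(
    mk_rows(up, "UP", up_sensor, keep),
    mk_rows(mhr, "MHR", rep("ECG", n), keep)))
  tall <- data.table::rbindlist(rows)

  # duplicate timestamps: an earlier corrupted copy of some rows, so the
  # highest-row (true) value must win at parse time
  if (cfg$duplicate_rate > 0 && nrow(tall) > 0) {
    ndup <- rbinom(1, nrow(tall), cfg$duplicate_rate)
    if (ndup > 0) {
      di <- sample.int(nrow(tall), ndup)
      bad <- tall[di]
      bad[, reading := reading + 7.5]
      tall <- data.table::rbindlist(list(bad, tall))
    }
  }

  truth_events <- data.table::rbindlist(list(
    if (nrow(accels)) data.table::data.table(
      type = "ACC", start_s = accels$time_s,
      end_s = accels$time_s + accels$duration, height = accels$height),
    if (nrow(decels)) data.table::data.table(
      type = "DEC", start_s = decels$time_s,
      end_s = decels$time_s + decels$duration, height = decels$depth),
    if (nrow(cons)) data.table::data.table(
      type = "CON", start_s = cons$time_s,
      end_s = cons$time_s + cons$width, height = cons$height)),
    fill = TRUE)

  out <- list(rows = tall, guid = cfg$guid,
              truth = list(events = as.data.frame(truth_events),
                           gaps = gp, mhr_capture = mc,
                           dropouts = sort(drop_idx)))
  if (!is.null(path)) {
    hdr <- data.table::copy(tall)
    data.table::setnames(hdr, c("Tracing GUID", "Trace DT", "Recorded DT",
                                "Measurement", "Sensor", "Monitor",
                                "Reading"))
    data.table::fwrite(hdr, path)
    out$path <- path
  }
  out
}

#' Write tall rows in the one-minute wide legacy format
#'
#' Groups each signal's samples into one-minute records of exactly 240
#' sample fields (4 samples/s for 60 s); slots with no sample are left
#' empty.  Exercises the legacy-format reader.
#'
#' @param rows tall data.table as produced by [simulate_tracing()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_wide_tracing <- function(rows, path) {
  dt <- data.table::as.data.table(rows)
  data.table::setnames(dt, canonical_columns(names(dt)))
  dt[, trace_dt := as.numeric(trace_dt)]
  # minute blocks: record timestamp = largest ms (earliest sample)
  dt[, block := floor((trace_dt - 1e-6) / 60000)]
  dt[, slot := as.integer(round(((block + 1) * 60000 - trace_dt) / 250)) +
       1L]
  dt <- dt[slot >= 1L & slot <= legacy_samples_per_record()]
  wide <- data.table::dcast(
    dt, tracing_guid + measurement + sensor + monitor + block ~ slot,
    value.var = "reading", fun.aggregate = function(v) v[length(v)])
  slot_cols <- setdiff(names(wide),
                       c("tracing_guid", "measurement", "sensor",
                         "monitor", "block"))
  missing_slots <- setdiff(as.character(seq_len(legacy_samples_per_record())),
                           slot_cols)
  for (mcol in missing_slots) wide[, (mcol) := NA_real_]
  data.table::setcolorder(
    wide, c("tracing_guid", "measurement", "sensor", "monitor", "block",
            as.character(seq_len(legacy_samples_per_record()))))
  wide[, trace_dt := (block + 1) * 60000]
  wide[, recorded_dt := trace_dt]
  wide[, block := NULL]
  data.table::setcolorder(
    wide, c("tracing_guid", "trace_dt", "recorded_dt", "measurement",
            "sensor", "monitor"))
  data.table::setnames(
    wide, c("tracing_guid", "trace_dt", "recorded_dt", "measurement",
            "sensor", "monitor",
            sprintf("sample_%03d", seq_len(legacy_samples_per_record()))))
  data.table::fwrite(wide, path)
  invisible(path)
}

group_names <- function() c(
  "PERINATAL_HIE", "ACIDOSIS_NO_HIE", "HEALTHY_NO_BG",
  "HEALTHY_NO_ACIDOSIS", "INTERVENTION_NO_BG",
  "INTERVENTION_NO_ACIDOSIS", "DISTANT_HIE", "DEATH_UNDER_6H")

# Draw one infant record satisfying the target group's definition with
# margins away from every decision boundary.
draw_record <- function(id, group, boundary = FALSE) {
  cord <- function(ph, bd) data.frame(source = "arterial", pH = ph,
                                      base_deficit = bd)
  acidotic_gas <- function() {
    if (boundary) cord(7.00, 10.0)
    else if (runif(1) < 0.5) cord(runif(1, 6.7, 6.93), runif(1, 4, 9))
    else cord(runif(1, 7.05, 7.2), runif(1, 10.5, 16))
  }
  normal_gas <- function() cord(runif(1, 7.15, 7.4), runif(1, 1, 8))
  base <- infant_record(id)
  rec <- switch(group,
    PERINATAL_HIE = infant_record(id, cord_gases = acidotic_gas(),
      ene_abnormal_items = sample(1:6, 1), ene_recorded = TRUE,
      hypothermia = TRUE, seizures_first_24h = runif(1) < 0.5,
      abnormal_exam_ge_6h = runif(1) < 0.5,
      apgar5 = sample(0:6, 1), nicu_admit = TRUE,
      discharged_home = FALSE),
    ACIDOSIS_NO_HIE = infant_record(id, cord_gases = acidotic_gas(),
      ene_abnormal_items = 0L, ene_recorded = TRUE,
      apgar5 = sample(7:10, 1)),
    HEALTHY_NO_BG = base,
    HEALTHY_NO_ACIDOSIS = infant_record(id, cord_gases = normal_gas(),
      apgar5 = sample(7:10, 1)),
    INTERVENTION_NO_BG = infant_record(id, nicu_admit = TRUE,
      apgar5 = sample(0:6, 1)),
    INTERVENTION_NO_ACIDOSIS = infant_record(id,
      cord_gases = normal_gas(), nicu_admit = TRUE,
      apgar5 = sample(0:6, 1)),
    DISTANT_HIE = infant_record(id, cord_gases = normal_gas(),
      nicu_admit = TRUE, hie_imaging_pattern = TRUE),
    DEATH_UNDER_6H = infant_record(id, cord_gases = acidotic_gas(),
      death_age_h = runif(1, 0.2, 5.5), nicu_admit = TRUE,
      discharged_home = FALSE, death_or_transfer = TRUE),
    stop("unknown group: ", group))
  rec
}

#' Simulate a clinical cohort spanning the study groups
#'
#' Draws infant records constructed to satisfy each target group's
#' printed definition with margins away from the decision boundaries,
#' and returns the true labels for round-trip testing of the classifier.
#'
#' @param n number of infants.
#' @param mix named numeric vector of group proportions (must sum to 1);
#'   default uniform over the eight groups.
#' @param seed RNG seed.
#' @param boundary_stress also plant boundary cases (cord pH exactly
#'   7.00, BD exactly 10), flagged in the truth table (default FALSE).
#' @return a list: `records` (list of [infant_record()]), `truth`
#'   (data.frame `infant_id`, `group`, `boundary`).
#' @export
simulate_cohort <- function(n, mix = NULL, seed = 1L,
                            boundary_stress = FALSE) {
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)
  if (is.null(mix)) {
    mix <- rep(1 / 8, 8)
    names(mix) <- group_names()
  }
  if (abs(sum(mix) - 1) > 1e-6) stop("mix must sum to 1")
  groups <- sample(names(mix), n, replace = TRUE, prob = mix)
  boundary <- if (boundary_stress)
    runif(n) < 0.1 & groups %in% c("PERINATAL_HIE", "ACIDOSIS_NO_HIE")
  else rep(FALSE, n)
  ids <- sprintf("INF%06d", seq_len(n))
  records <- lapply(seq_len(n), function(i)
    draw_record(ids[i], groups[i], boundary[i]))
  list(records = records,
       truth = data.frame(infant_id = ids, group = groups,
                          boundary = boundary,
                          stringsAsFactors = FALSE))
}
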