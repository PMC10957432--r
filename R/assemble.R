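# Sensor precedence for combination: the more accurate (internal) sensor
# wins wherever two channels overlap.  FECG beats external ultrasound for
# fetal heart rate; the intrauterine pressure catheter beats the TOCO.
fhr_sensor_rank <- function(sensor) ifelse(sensor == "FECG", 2L, 1L)
ua_sensor_rank <- function(sensor) ifelse(sensor == "Internal", 2L, 1L)

# Merge channels pointwise: at each timestamp keep the sample from the
# highest-precedence sensor; among equals prefer the HR2 receptacle.
merge_channels <- function(channels, rank_fun, out_measurement, units) {
  if (length(channels) == 0L) return(NULL)
  tabs <- lapply(channels, function(s) {
    if (n_samples(s) == 0L) return(NULL)
    data.table::data.table(
      time = sample_times(s), value = s$data,
      sensor = sample_sensors(s),
      monitor = sample_monitors(s),
      receptacle = s$measurement)
  })
  tab <- data.table::rbindlist(tabs)
  if (is.null(tab) || nrow(tab) == 0L) return(NULL)
  delta <- channels[[1]]$delta
  tab[, rank := rank_fun(sensor)]
  tab[, hr2 := as.integer(receptacle == "HR2")]
  # snap to a common integer grid for exact timestamp matching
  tab[, grid := round(time / delta)]
  data.table::setorder(tab, grid, rank, hr2)
  tab <- tab[, .SD[.N], by = grid]   # highest (rank, hr2) wins
  data.table::setorder(tab, grid)
  build_segmented(tab$grid * delta, tab$value, delta, out_measurement,
                  units, tab$sensor, tab$monitor)
}

#' Combine per-sensor channels into single FHR, UA and MHR signals
#'
#' A raw record often carries the same physiological measurement from
#' different sensors at different times (external ultrasound early in
#' labor, fetal scalp ECG near birth; TOCO then intrauterine catheter).
#' This merges the channels into one signal per measurement, giving the
#' more accurate sensor precedence wherever channels overlap, and keeps
#' per-sample sensor provenance (segments split at sensor switches).
#'
#' @param raw an `efm_record` at stage `"raw"` (a combined record passes
#'   through unchanged up to re-keying: combination is idempotent).
#' @return an `efm_record` at stage `"combined"` with at most one signal
#'   per measurement, keyed `FHR`, `UA`, `MHR`.
#' @export
combine_sensors <- function(raw) {
  meas <- vapply(raw$signals, function(s) s$measurement, "")
  fhr <- merge_channels(raw$signals[meas %in% c("HR1", "HR2", "FHR")],
                        fhr_sensor_rank, "FHR", "BPM")
  ua <- merge_channels(raw$signals[meas %in% c("UP", "UA")],
                       ua_sensor_rank, "UA", "0-100")
  mhr <- merge_channels(raw$signals[meas == "MHR"],
                        function(s) 1L, "MHR", "BPM")
  sigs <- list(FHR = fhr, UA = ua, MHR = mhr)
  sigs <- sigs[!vapply(sigs, is.null, TRUE)]
  prov <- raw$provenance
  if (!"FHR" %in% names(sigs))
    prov <- paste(prov, "[flag: no FHR channel]")
  efm_record(raw$guid, sigs, stage = "combined", provenance = prov)
}

# Content identity of two records: same signals, same samples, same times.
record_identical <- function(a, b) {
  if (!setequal(names(a$signals), names(b$signals))) return(FALSE)
  for (nm in names(a$signals)) {
    sa <- a$signals[[nm]]; sb <- b$signals[[nm]]
    if (n_samples(sa) != n_samples(sb)) return(FALSE)
    if (!isTRUE(all.equal(sa$data, sb$data))) return(FALSE)
    if (!isTRUE(all.equal(sample_times(sa), sample_times(sb),
                          tolerance = time_tol(sa$delta)))) return(FALSE)
  }
  TRUE
}

record_time_range <- function(rec) {
  tt <- unlist(lapply(rec$signals, function(s) {
    if (n_samples(s) == 0L) return(NULL)
    c(min(sample_times(s)), max(sample_times(s)))
  }), use.names = FALSE)
  if (is.null(tt)) return(c(NA_real_, NA_real_))
  range(tt)
}

#' Detect duplicate and conflicting tracing files for one infant
#'
#' Several tracing files can be linked to the same pregnancy.  Exact
#' content duplicates keep one representative (the lexicographically
#' lowest GUID) and mark the rest as duplicates.  Distinct files whose
#' time ranges overlap are conflicting versions of the same labor: all are
#' marked "special" and set aside.  More than one distinct, non-overlapping
#' non-duplicate file cannot be attributed to the labor either: all are
#' excluded.
#'
#' @param candidates list of `efm_record` objects linked to one infant.
#' @return a list of character GUID vectors: `retained`, `duplicate`,
#'   `special`, `excluded`.
#' @export
detect_duplicate_tracings <- function(candidates) {
  stopifnot(length(candidates) >= 1L)
  guids <- vapply(candidates, function(r) r$guid, "")
  out <- list(retained = character(0), duplicate = character(0),
              special = character(0), excluded = character(0))
  # group by content identity; representative = lowest guid in group
  group <- integer(length(candidates))
  reps <- integer(0)
  for (i in seq_along(candidates)) {
    assigned <- FALSE
    for (g in seq_along(reps)) {
      if (record_identical(candidates[[i]], candidates[[reps[g]]])) {
        group[i] <- g; assigned <- TRUE; break
      }
    }
    if (!assigned) { reps <- c(reps, i); group[i] <- length(reps) }
  }
  rep_idx <- vapply(seq_along(reps), function(g) {
    members <- which(group == g)
    members[order(guids[members])[1L]]
  }, 1L)
  dup_idx <- setdiff(seq_along(candidates), rep_idx)
  out$duplicate <- guids[dup_idx]
  if (length(rep_idx) == 1L) {
    out$retained <- guids[rep_idx]
    return(out)
  }
  ranges <- lapply(candidates[rep_idx], record_time_range)
  overlap <- FALSE
  for (i in seq_along(rep_idx)) for (j in seq_along(rep_idx)) {
    if (i < j && ranges[[i]][1] <= ranges[[j]][2] &&
        ranges[[j]][1] <= ranges[[i]][2]) overlap <- TRUE
  }
  if (overlap) out$special <- guids[rep_idx]
  else out$excluded <- guids[rep_idx]
  out
}

#' Split a tracing spanning several pregnancies
#'
#' Some tracing files concatenate data from several of one mother's
#' pregnancies.  Each sample is assigned to the nearest following birth
#' within the retention window; samples matching no birth are discarded,
#' and per-pregnancy signals are re-referenced to their own birth time
#' (birth = 0, earlier samples negative).
#'
#' @param sig a `seg_signal` whose times are on a common absolute clock
#'   (seconds) shared with `birth_times`.
#' @param birth_times sorted numeric vector of birth times on that clock.
#' @param window_h retention window in hours (default 72).
#' @return a list, one `seg_signal` per birth that received samples, named
#'   by the birth time.
#' @export
split_concatenated_pregnancies <- function(sig, birth_times, window_h = 72) {
  if (length(birth_times) == 0L) stop("empty birth list")
  birth_times <- sort(birth_times)
  tt <- sample_times(sig)
  if (length(tt) == 0L) return(list())
  # index of nearest birth at or after each sample
  tol <- time_tol(sig$delta)
  nxt <- findInterval(tt - tol, birth_times) + 1L
  ok <- nxt >= 1L & nxt <= length(birth_times)
  ok[ok] <- (birth_times[nxt[ok]] - tt[ok]) <= window_h * 3600 +
    time_tol(sig$delta)
  out <- list()
  sens <- sample_sensors(sig)
  mons <- sample_monitors(sig)
  for (b in unique(nxt[ok])) {
    sel <- ok & nxt == b
    out[[as.character(birth_times[b])]] <-
      build_segmented(tt[sel] - birth_times[b], sig$data[sel], sig$delta,
                      sig$measurement, sig$units, sens[sel], mons[sel])
  }
  out
}
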