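#' Open (create) a CSV-backed catalog
#'
#' The catalog is a directory of CSV tables mirroring the relational
#' schemas that track tracing processing (status, per-signal and
#' per-segment statistics, events, per-epoch features, processing log).
#' Every table is stored as one RFC 4180 CSV file, readable by any SQL
#' loader; re-running a processing step upserts the status row for a
#' tracing rather than duplicating it.
#'
#' @param dir directory path; created if absent.
#' @return an object of class `ctg_catalog`.
#' @export
catalog_open <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir), class = "ctg_catalog")
}

catalog_path <- function(cat, table) file.path(cat$dir, paste0(table, ".csv"))

#' Read a catalog table
#' @param cat a `ctg_catalog`.
#' @param table table name (e.g. `"CTG_Status"`, `"Event"`).
#' @return data.frame, or a zero-row data.frame if the table is absent.
#' @export
catalog_read <- function(cat, table) {
  p <- catalog_path(cat, table)
  if (!file.exists(p)) return(data.frame())
  as.data.frame(data.table::fread(p, showProgress = FALSE))
}

# Upsert rows into a table by key columns; appends when key is NULL.
catalog_upsert <- function(cat, table, rows, key = NULL) {
  rows <- data.table::as.data.table(rows)
  existing <- data.table::as.data.table(catalog_read(cat, table))
  if (nrow(existing) && !is.null(key)) {
    keep <- !do.call(paste, existing[, key, with = FALSE]) %in%
      do.call(paste, rows[, key, with = FALSE])
    existing <- existing[keep]
  }
  out <- data.table::rbindlist(list(existing, rows), fill = TRUE)
  data.table::fwrite(out, catalog_path(cat, table))
  invisible(out)
}

# Per-signal and per-segment statistics of one record.
signal_stats_rows <- function(rec) {
  rows <- lapply(names(rec$signals), function(nm) {
    s <- rec$signals[[nm]]
    data.frame(guid = rec$guid, stage = rec$stage, signal = nm,
               measurement = s$measurement, n_segments = n_segments(s),
               n_samples = n_samples(s),
               start_s = if (n_segments(s)) s$seg_start[1] else NA_real_,
               end_s = if (n_segments(s))
                 s$seg_start[n_segments(s)] +
                 s$seg_len[n_segments(s)] * s$delta else NA_real_)
  })
  do.call(rbind, rows)
}

segment_stats_rows <- function(rec) {
  rows <- lapply(names(rec$signals), function(nm) {
    s <- rec$signals[[nm]]
    if (n_segments(s) == 0L) return(NULL)
    data.frame(guid = rec$guid, stage = rec$stage, signal = nm,
               segment = seq_len(n_segments(s)),
               start_s = s$seg_start, n_samples = s$seg_len,
               onset_pointer = onset_pointers(s),
               sensor = seg_sensors(s), monitor = seg_monitors(s))
  })
  do.call(rbind, rows)
}

#' Record a processing step's outputs in the catalog
#'
#' Writes/updates the status, signal and segment statistics for the
#' record, appends one `Processing` row, and stores any events and
#' per-epoch features.  Event and feature rows for the same tracing are
#' replaced on re-run, so the store never accumulates duplicates.
#'
#' @param cat a `ctg_catalog` from [catalog_open()].
#' @param record an `efm_record` at any stage.
#' @param events optional event table for the tracing.
#' @param features optional per-epoch feature table.
#' @param step processing step name logged in `Processing` (defaults to
#'   the record's stage).
#' @return the catalog, invisibly.
#' @export
write_catalog <- function(cat, record, events = NULL, features = NULL,
                          step = record$stage) {
  status <- data.frame(guid = record$guid, stage = record$stage,
                       n_signals = length(record$signals),
                       updated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                       source = record$provenance)
  catalog_upsert(cat, "CTG_Status", status, key = "guid")
  catalog_upsert(cat, "signalStats", signal_stats_rows(record),
                 key = c("guid", "stage", "signal"))
  seg <- segment_stats_rows(record)
  if (!is.null(seg)) {
    existing <- catalog_read(cat, "segmentStats")
    if (nrow(existing))
      existing <- existing[!(existing$guid == record$guid &
                               existing$stage == record$stage), ,
                           drop = FALSE]
    data.table::fwrite(rbind(existing, seg),
                       catalog_path(cat, "segmentStats"))
  }
  starts <- vapply(record$signals, function(s)
    if (n_segments(s)) s$seg_start[1] else NA_real_, 1)
  catalog_upsert(cat, "DomainStart",
                 data.frame(guid = record$guid, stage = record$stage,
                            domain_start_s = suppressWarnings(
                              min(starts, na.rm = TRUE))),
                 key = c("guid", "stage"))
  proc <- data.frame(guid = record$guid, step = step,
                     completed = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  catalog_upsert(cat, "Processing", proc, key = c("guid", "step"))
  if (!is.null(events) && nrow(events)) {
    catalog_upsert(cat, "Event_Type",
                   data.frame(event_type_id = seq_along(
                     c("BAS", "ACC", "DEC", "CON", "NOI", "RIN")),
                     code = c("BAS", "ACC", "DEC", "CON", "NOI", "RIN")),
                   key = "code")
    catalog_upsert(cat, "Event", events, key = "guid")
  }
  if (!is.null(features) && nrow(features))
    catalog_upsert(cat, "features4epoch", features, key = "guid")
  invisible(cat)
}

#' Load the events of one tracing back from the catalog
#' @param cat a `ctg_catalog`.
#' @param guid tracing identifier.
#' @return data.frame of events.
#' @export
catalog_events <- function(cat, guid) {
  ev <- catalog_read(cat, "Event")
  if (!nrow(ev)) return(ev)
  ev[ev$guid == guid, , drop = FALSE]
}

#' Per-hour coverage curves by study group
#'
#' For each hour bin in the 72 hours before birth, the fraction of
#' records (per group) having at least one sample of both FHR and UA in
#' that bin — the standard way to visualize how much monitoring the
#' groups received as a function of time before birth.
#'
#' @param records list of combined/repaired `efm_record` objects.
#' @param groups character vector of group labels, one per record.
#' @param window_h span in hours (default 72).
#' @return data.frame: `group`, `hour_start` (e.g. -72 ... -1),
#'   `fraction`.
#' @export
coverage_curve <- function(records, groups, window_h = 72) {
  stopifnot(length(records) == length(groups))
  bins <- -(window_h:1)
  has_bin <- function(sig, h0) {
    if (is.null(sig) || n_samples(sig) == 0L) return(FALSE)
    iv <- support_intervals(sig)
    any(iv[, "start"] < (h0 + 1) * 3600 & iv[, "end"] > h0 * 3600)
  }
  out <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) == 0L) { warning("empty group: ", g); next }
    frac <- vapply(bins, function(h0) {
      mean(vapply(records[idx], function(r)
        has_bin(r$signals$FHR, h0) && has_bin(r$signals$UA, h0), TRUE))
    }, 1)
    out[[g]] <- data.frame(group = g, hour_start = bins, fraction = frac)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Per-epoch coverage of each signal in a record
#'
#' Fraction of each 20-minute epoch covered by stored samples, per
#' signal.
#'
#' @param record an `efm_record` at any stage.
#' @param epoch_s epoch length in seconds (default 1200).
#' @return data.frame: `signal`, `epoch_index`, `start_s`, `end_s`,
#'   `coverage`.
#' @export
signal_coverage_epochs <- function(record, epoch_s = 1200) {
  rows <- list()
  for (nm in names(record$signals)) {
    s <- record$signals[[nm]]
    if (n_samples(s) == 0L) next
    tt <- sample_times(s)
    first_epoch <- floor(-min(tt) / epoch_s - 1e-9)
    n_full <- epoch_s / s$delta
    for (k in first_epoch:0) {
      e0 <- -(k + 1) * epoch_s; e1 <- -k * epoch_s
      n_in <- sum(tt >= e0 - time_tol(s$delta) &
                    tt < e1 - time_tol(s$delta))
      rows[[length(rows) + 1L]] <-
        data.frame(signal = nm, epoch_index = k, start_s = e0,
                   end_s = e1, coverage = n_in / n_full)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
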