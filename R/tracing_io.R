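#' @import data.table
NULL

# Tall tracing-file column set (canonical names, in file order).
TALL_COLUMNS <- c("tracing_guid", "trace_dt", "recorded_dt", "measurement",
                  "sensor", "monitor", "reading")

# One-minute legacy records carry 240 sample values (60 s at 4 samples/s).
#' Number of sample fields in a one-minute legacy tracing record
#' @export
legacy_samples_per_record <- function() 240L

#' Normalize maternal medical record numbers
#'
#' Raw MRNs arrive as 7, 8 or 12 digit strings: 12-digit values carry the
#' "1100" institutional prefix, 8-digit values lack it, and 7-digit values
#' additionally lost a leading zero.  Normalization left-pads 7-digit
#' values to 8 digits and prepends "1100" to 8-digit values, so every
#' accepted identifier is exactly 12 digits.  Values containing nonnumeric
#' characters, or with fewer than 7 or more than 12 digits, are rejected
#' unchanged.  Lengths 9-11 match no known MRN form and are rejected as
#' length errors.
#'
#' @param raw character vector of raw MRN strings.
#' @return a data.frame with columns `raw`, `mrn` (normalized 12-digit
#'   identifier, or `NA` when rejected) and `status` (`"ok"`,
#'   `"nonnumeric"` or `"length"`).
#' @examples
#' normalize_mrn(c("12345678", "1234567", "110012345678", "11A2345678"))
#' @export
normalize_mrn <- function(raw) {
  raw <- trimws(as.character(raw))
  status <- rep("ok", length(raw))
  mrn <- rep(NA_character_, length(raw))
  nonnum <- !grepl("^[0-9]+$", raw)
  status[nonnum] <- "nonnumeric"
  len <- nchar(raw)
  badlen <- !nonnum & !(len %in% c(7L, 8L, 12L))
  status[badlen] <- "length"
  ok <- status == "ok"
  m <- raw[ok]
  l <- nchar(m)
  m[l == 7L] <- paste0("0", m[l == 7L])
  l <- nchar(m)
  m[l == 8L] <- paste0("1100", m[l == 8L])
  mrn[ok] <- m
  data.frame(raw = raw, mrn = mrn, status = status,
             stringsAsFactors = FALSE)
}

# A reading is "valid" when present, numeric, and physically plausible for
# its measurement: heart rates 0-300 bpm (0 = dropout marker, still a
# stored sample), uncalibrated uterine pressure 0-100.
valid_reading <- function(reading, measurement) {
  v <- suppressWarnings(as.numeric(reading))
  ok <- !is.na(v)
  hr <- measurement %in% c("HR1", "HR2", "MHR", "FHR")
  ok & ((hr & v >= 0 & v <= 300) | (!hr & v >= 0 & v <= 100))
}

#' Resolve multiple samples sharing one timestamp
#'
#' When monitor-to-server communication is interrupted, packets are resent
#' and several rows of the same signal can carry the same timestamp.  The
#' resolution rule: if no reading is valid the sample is dropped; if
#' exactly one is valid it is kept; if several valid readings disagree the
#' one from the highest row index is kept, as it is likely a corrected
#' value.
#'
#' @param readings vector of raw readings at one (signal, timestamp).
#' @param row_index integer file-row positions of those readings.
#' @param measurement measurement name (determines the validity range).
#' @return the selected numeric reading, or `NA` if all readings were
#'   invalid (sample dropped).
#' @export
resolve_duplicate_timestamps <- function(readings, row_index, measurement) {
  ok <- valid_reading(readings, rep(measurement[1], length(readings)))
  if (!any(ok)) return(NA_real_)
  keep <- which(ok)[which.max(row_index[ok])]
  as.numeric(readings[keep])
}

#' Apply the 72-hour pre-birth retention window
#'
#' Samples recorded earlier than `window_h` hours before birth are not
#' retained.  A tracing whose samples all fall outside the window is
#' excluded entirely.
#'
#' @param sig a `seg_signal` with times in seconds relative to birth.
#' @param window_h window length in hours (default 72).
#' @return a list with `signal` (the truncated `seg_signal`, or `NULL`
#'   when nothing remains) and `status` (`"matched"` or
#'   `"outside_window_prior"`).
#' @export
apply_birth_window <- function(sig, window_h = 72) {
  cutoff <- -window_h * 3600
  tt <- sample_times(sig)
  keep <- tt >= cutoff - time_tol(sig$delta)
  if (!any(keep))
    return(list(signal = NULL, status = "outside_window_prior"))
  if (all(keep)) return(list(signal = sig, status = "matched"))
  out <- build_segmented(tt[keep], sig$data[keep], sig$delta,
                         sig$measurement, sig$units,
                         sample_sensors(sig)[keep],
                         sample_monitors(sig)[keep])
  list(signal = out, status = "matched")
}

# Map arbitrary header spellings onto the canonical tall column names.
canonical_columns <- function(nms) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
  lookup <- c(tracingguid = "tracing_guid", traceidentifier = "tracing_guid",
              guid = "tracing_guid",
              tracedt = "trace_dt", recordeddt = "recorded_dt",
              measurement = "measurement", sensor = "sensor",
              monitor = "monitor", reading = "reading")
  out <- lookup[key]
  out[is.na(out)] <- nms[is.na(out)]
  unname(out)
}

#' Parse a tall per-sample tracing CSV into a raw EFM record
#'
#' Reads a deidentified tall tracing file (one sample per row; times given
#' as non-negative milliseconds before birth), groups samples into one
#' channel per unique measurement/sensor/monitor combination, resolves
#' duplicate timestamps, and builds segmented signals.  Internally all
#' times become signed seconds relative to birth (negative before birth).
#'
#' @param path path to the CSV file.
#' @param delta sampling increment in seconds.
#' @param window_h pre-birth retention window in hours.
#' @return a list with `record` (an `efm_record` at stage `"raw"`, or
#'   `NULL`), `status` (a linkage-disposition string) and `report` (named
#'   row-disposition counts that sum to the file's row count).
#' @export
parse_tracing_csv <- function(path, delta = 0.25, window_h = 72) {
  dt <- data.table::fread(path, colClasses = list(character = 1),
                          showProgress = FALSE)
  data.table::setnames(dt, canonical_columns(names(dt)))
  missing_cols <- setdiff(TALL_COLUMNS, names(dt))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  report <- c(rows_total = nrow(dt), rows_malformed_timestamp = 0L,
              rows_invalid_reading = 0L, rows_duplicate_dropped = 0L,
              rows_outside_window = 0L, rows_kept = 0L)
  if (nrow(dt) == 0L)
    return(list(record = NULL, status = "empty_file", report = report))
  guid <- dt$tracing_guid[1]
  dt[, row_index := .I]
  # timestamps: non-negative ms before birth, on the sampling grid
  ms <- suppressWarnings(as.numeric(dt$trace_dt))
  grid_ms <- delta * 1000
  bad_ts <- is.na(ms) | ms < 0 |
    abs(ms / grid_ms - round(ms / grid_ms)) > 0.01
  report["rows_malformed_timestamp"] <- sum(bad_ts)
  dt <- dt[!bad_ts]
  ms <- ms[!bad_ts]
  if (nrow(dt) == 0L)
    return(list(record = NULL, status = "error", report = report))
  dt[, time_s := -round(ms / grid_ms) * delta]
  dt[, valid := valid_reading(reading, measurement)]

  # duplicate-timestamp resolution within each signal identity
  dt[, sig_key := paste(measurement, sensor, monitor, sep = "|")]
  resolved <- dt[, {
    v <- resolve_duplicate_timestamps(reading, row_index, measurement)
    list(value = v)
  }, by = .(sig_key, measurement, sensor, monitor, time_s)]
  resolved <- resolved[!is.na(value)]
  n_valid_rows <- sum(dt$valid)
  report["rows_invalid_reading"] <- nrow(dt) - n_valid_rows
  # valid rows superseded by a higher-row duplicate at the same timestamp
  report["rows_duplicate_dropped"] <- n_valid_rows - nrow(resolved)

  # retention window
  outside <- resolved$time_s < -window_h * 3600 - time_tol(delta)
  report["rows_outside_window"] <- sum(outside)
  resolved <- resolved[!outside]
  if (nrow(resolved) == 0L)
    return(list(record = NULL, status = "outside_window_prior",
                report = report))
  report["rows_kept"] <- nrow(resolved)

  data.table::setorder(resolved, sig_key, time_s)
  sigs <- lapply(split(resolved, resolved$sig_key), function(g) {
    units <- if (g$measurement[1] %in% c("UP", "UA")) "0-100" else "BPM"
    build_segmented(g$time_s, g$value, delta, g$measurement[1], units,
                    g$sensor[1], g$monitor[1])
  })
  rec <- efm_record(guid, sigs, stage = "raw", provenance = path)
  list(record = rec, status = "matched", report = report)
}

#' Write a parse/disposition report
#'
#' Serializes the row-disposition counts from [parse_tracing_csv()] (or
#' an aggregated batch of them) as JSON or CSV.
#'
#' @param report named counts, or a data.frame of per-file counts.
#' @param path output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_parse_report <- function(report, path,
                               format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(as.list(report), path, auto_unbox = TRUE)
  } else {
    df <- if (is.data.frame(report)) report
      else as.data.frame(as.list(report))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a one-minute wide legacy tracing file
#'
#' The legacy server format stores one minute of signal per record: the
#' identifying fields followed by exactly 240 sample values (4 samples/s
#' for 60 s).  This reader converts such files to the tall one-sample-per-
#' row representation consumed by [parse_tracing_csv()].
#'
#' @param path path to the wide-format CSV.
#' @return a data.table in tall format with the canonical seven columns.
#' @export
read_wide_tracing <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = 1),
                          showProgress = FALSE)
  data.table::setnames(dt, canonical_columns(names(dt)))
  sample_cols <- grep("^sample", names(dt), value = TRUE)
  if (length(sample_cols) != legacy_samples_per_record())
    stop(sprintf("legacy record must carry exactly %d sample fields, found %d",
                 legacy_samples_per_record(), length(sample_cols)))
  long <- data.table::melt(
    dt, id.vars = setdiff(names(dt), sample_cols),
    measure.vars = sample_cols, variable.name = "slot",
    value.name = "reading", variable.factor = FALSE)
  slot_idx <- as.integer(sub("^sample_?", "", long$slot))
  # record timestamp marks the first sample of the minute; later samples
  # are closer to birth, so ms-before-birth decreases along the record
  long[, trace_dt := as.numeric(trace_dt) - (slot_idx - 1L) * 250]
  long[, recorded_dt := as.numeric(recorded_dt) - (slot_idx - 1L) * 250]
  long <- long[!is.na(reading) & reading != ""]
  long[, slot := NULL]
  data.table::setcolorder(long, TALL_COLUMNS)
  long[]
}
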