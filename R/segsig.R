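#' @importFrom stats approx coef fft fitted lm median quantile rbinom
#'   rnorm runif sd var
#' @importFrom Rcpp evalCpp
#' @useDynLib ctgkit, .registration = TRUE
NULL

# Absolute tolerance used for all floating-point time comparisons: delta/100.
time_tol <- function(delta) delta / 100

#' Segmented signal container
#'
#' A `seg_signal` stores a gappy, regularly sampled signal as the
#' concatenation of its contiguous segments plus per-segment bookkeeping:
#' the start time of each segment (seconds relative to birth, with times
#' before birth negative), the number of samples in each segment, and the
#' sensor/monitor that produced it.  This mirrors the efficient
#' segment-pointer storage used for electronic fetal monitoring signals,
#' where sensor disconnects and transmission problems leave frequent gaps.
#'
#' @param data numeric vector of concatenated sample values for all
#'   segments, in time order.
#' @param seg_start numeric vector of segment start times in seconds
#'   relative to birth (negative before birth).
#' @param seg_len integer vector of samples per segment; must sum to
#'   `length(data)`.
#' @param delta sampling increment in seconds (default 0.25, i.e. 4 Hz).
#' @param measurement signal name, e.g. `"HR1"`, `"HR2"`, `"MHR"`, `"UP"`,
#'   `"FHR"`, `"UA"`.
#' @param units unit string (`"BPM"` for heart rates, `"0-100"` for
#'   uncalibrated uterine pressure).
#' @param sensor character vector naming the sensor: `"external"`,
#'   `"FECG"`, `"TOCO"`, `"Internal"`, `"ECG"` or `"unknown"`.  Length 1,
#'   one per segment, or one per sample: provenance is tracked
#'   sample-by-sample so a sensor switch inside a contiguous run does not
#'   force an artificial gap.
#' @param monitor character vector naming the monitor model (recycled like
#'   `sensor`).
#' @return an object of class `seg_signal`.
#' @examples
#' s <- seg_signal(rnorm(48, 140, 5), seg_start = c(-60, -20),
#'                 seg_len = c(24, 24), measurement = "FHR")
#' n_segments(s)
#' find_gaps(s)
#' @export
seg_signal <- function(data, seg_start, seg_len, delta = 0.25,
                       measurement = "FHR", units = "BPM",
                       sensor = "unknown", monitor = "unknown") {
  seg_len <- as.integer(seg_len)
  nseg <- length(seg_len)
  if (length(seg_start) != nseg)
    stop("seg_start and seg_len must have equal length")
  if (nseg > 0 && any(seg_len < 1L))
    stop("every segment must contain at least one sample")
  if (sum(seg_len) != length(data))
    stop("sum(seg_len) must equal length(data)")
  n <- length(data)
  expand_label <- function(lab) {
    if (length(lab) == n) as.character(lab)
    else if (length(lab) == nseg) rep(as.character(lab), seg_len)
    else if (length(lab) == 1L) rep(as.character(lab), n)
    else stop("sensor/monitor must have length 1, n_segments or n_samples")
  }
  if (nseg > 1) {
    seg_end <- seg_start + seg_len * delta
    # segments must be ordered and separated by >= one missing sample slot
    if (any(seg_start[-1] - seg_end[-nseg] < delta - time_tol(delta)))
      stop("segments must be disjoint, ordered, and separated by a gap")
  }
  structure(list(
    measurement = measurement, units = units, delta = delta,
    data = as.numeric(data),
    seg_start = as.numeric(seg_start), seg_len = seg_len,
    sample_sensor = expand_label(sensor),
    sample_monitor = expand_label(monitor)
  ), class = "seg_signal")
}

#' @export
print.seg_signal <- function(x, ...) {
  cat(sprintf("<seg_signal> %s [%s], delta = %gs\n",
              x$measurement, x$units, x$delta))
  cat(sprintf("  %d segment(s), %d samples, support [%.2f, %.2f] s\n",
              n_segments(x), n_samples(x),
              if (n_segments(x)) min(x$seg_start) else NA_real_,
              if (n_segments(x)) max(x$seg_start + x$seg_len * x$delta)
              else NA_real_))
  invisible(x)
}

#' Number of segments / samples in a segmented signal
#' @param x a `seg_signal`.
#' @return integer count.
#' @export
n_segments <- function(x) length(x$seg_len)

#' @rdname n_segments
#' @export
n_samples <- function(x) length(x$data)

#' Segment onset pointers
#'
#' Index of the first sample of each segment within the concatenated data
#' vector.  `onset_pointers()` is 1-based (the natural R convention, and the
#' convention used when these structures are printed);
#' `onset_offsets()` gives the equivalent 0-based offsets.
#' @param x a `seg_signal`.
#' @return integer vector, one element per segment.
#' @export
onset_pointers <- function(x) {
  if (n_segments(x) == 0L) return(integer(0))
  cumsum(c(1L, x$seg_len[-n_segments(x)]))
}

#' @rdname onset_pointers
#' @export
onset_offsets <- function(x) onset_pointers(x) - 1L

#' Sample times of a segmented signal
#' @param x a `seg_signal`.
#' @return numeric vector, seconds relative to birth, one per stored sample.
#' @export
sample_times <- function(x) {
  if (n_segments(x) == 0L) return(numeric(0))
  unlist(lapply(seq_len(n_segments(x)), function(k)
    x$seg_start[k] + (seq_len(x$seg_len[k]) - 1L) * x$delta),
    use.names = FALSE)
}

#' Sensor and monitor provenance
#'
#' Provenance is tracked sample-by-sample (so the sensor in use can be
#' determined at any time point); the per-segment labels are those of each
#' segment's first sample.
#' @param x a `seg_signal`.
#' @return character vector: one label per sample (`sample_sensors`,
#'   `sample_monitors`) or per segment (`seg_sensors`, `seg_monitors`).
#' @export
sample_sensors <- function(x) x$sample_sensor

#' @rdname sample_sensors
#' @export
sample_monitors <- function(x) x$sample_monitor

#' @rdname sample_sensors
#' @export
seg_sensors <- function(x) x$sample_sensor[onset_pointers(x)]

#' @rdname sample_sensors
#' @export
seg_monitors <- function(x) x$sample_monitor[onset_pointers(x)]

#' Build a segmented signal from time-stamped samples
#'
#' Consecutive samples whose time step equals the sampling increment share a
#' segment; any step greater than one increment opens a new segment (a gap
#' has no minimum duration).  Zero-valued heart-rate samples are ordinary
#' stored samples here (monitor dropouts), not gaps.
#'
#' @param times strictly increasing sample times in seconds (relative to
#'   birth); all steps must be integer multiples of `delta` to within
#'   `delta/100`.
#' @param values numeric sample values, same length as `times`.
#' @param delta sampling increment in seconds.
#' @param sensor,monitor per-sample sensor/monitor labels (length 1 or
#'   `length(times)`); provenance is kept per sample, so a label change
#'   inside a contiguous run does not open a new segment.
#' @inheritParams seg_signal
#' @return a `seg_signal`.
#' @export
build_segmented <- function(times, values, delta = 0.25,
                            measurement = "FHR", units = "BPM",
                            sensor = "unknown", monitor = "unknown") {
  stopifnot(length(times) == length(values))
  if (length(times) == 0L)
    return(seg_signal(numeric(0), numeric(0), integer(0), delta,
                      measurement, units, character(0), character(0)))
  if (length(sensor) == 1L) sensor <- rep(sensor, length(times))
  if (length(monitor) == 1L) monitor <- rep(monitor, length(times))
  tol <- time_tol(delta)
  dt <- diff(times)
  if (any(dt <= tol)) stop("unsorted input")
  steps <- dt / delta
  if (any(abs(steps - round(steps)) > 0.01)) stop("off-grid sample")
  steps <- round(steps)
  # new segment wherever the step exceeds one increment
  brk <- steps > 1L
  seg_id <- cumsum(c(TRUE, brk))
  seg_len <- as.integer(tabulate(seg_id))
  first <- c(1L, which(brk) + 1L)
  seg_signal(values, times[first], seg_len, delta, measurement, units,
             sensor, monitor)
}

#' List the gaps in a segmented signal
#'
#' @param x a `seg_signal`.
#' @return a data.frame with one row per gap and columns `gap_start`,
#'   `gap_end` (half-open interval, seconds) and `duration`.  A single- or
#'   zero-segment signal has no gaps.
#' @export
find_gaps <- function(x) {
  nseg <- n_segments(x)
  if (nseg <= 1L)
    return(data.frame(gap_start = numeric(0), gap_end = numeric(0),
                      duration = numeric(0)))
  gap_start <- x$seg_start[-nseg] + x$seg_len[-nseg] * x$delta
  gap_end <- x$seg_start[-1]
  data.frame(gap_start = gap_start, gap_end = gap_end,
             duration = gap_end - gap_start)
}

#' Convert to and from a dense representation
#'
#' `to_dense()` expands a segmented signal onto the full sampling grid from
#' its first to its last sample, filling gap slots with `NA`; `from_dense()`
#' inverts it, using `NA` as the segment separator, so that
#' `from_dense(to_dense(x))` reproduces `x` exactly.
#'
#' @param x a `seg_signal`.
#' @return for `to_dense()`, a list with components `time` and `values`
#'   (equal-length numeric vectors, `NA` values marking gaps).
#' @export
to_dense <- function(x) {
  if (n_segments(x) == 0L) return(list(time = numeric(0), values = numeric(0)))
  t0 <- x$seg_start[1]
  nseg <- n_segments(x)
  t_end <- x$seg_start[nseg] + (x$seg_len[nseg] - 1L) * x$delta
  n <- round((t_end - t0) / x$delta) + 1L
  tim <- t0 + (seq_len(n) - 1L) * x$delta
  val <- rep(NA_real_, n)
  idx <- round((sample_times(x) - t0) / x$delta) + 1L
  val[idx] <- x$data
  list(time = tim, values = val)
}

#' @rdname to_dense
#' @param dense a list with `time` (regular grid) and `values` (`NA` in
#'   gaps), as produced by `to_dense()`.
#' @param delta sampling increment; checked against the dense time axis.
#' @inheritParams seg_signal
#' @export
from_dense <- function(dense, delta = 0.25, measurement = "FHR",
                       units = "BPM", sensor = "unknown",
                       monitor = "unknown") {
  tim <- dense$time; val <- dense$values
  stopifnot(length(tim) == length(val))
  if (length(tim) > 1L) {
    steps <- diff(tim) / delta
    if (any(abs(steps - 1) > 0.01)) stop("off-grid dense time axis")
  }
  keep <- !is.na(val)
  build_segmented(tim[keep], val[keep], delta, measurement, units,
                  sensor, monitor)
}

# Half-open support intervals [start, end) of each segment.
support_intervals <- function(x) {
  cbind(start = x$seg_start, end = x$seg_start + x$seg_len * x$delta)
}

#' Restrict two segmented signals to their common time support
#'
#' @param a,b `seg_signal` objects with equal sampling increments.
#' @return a list with elements `a` and `b`: the inputs restricted to the
#'   intersection of their supports.  Values are unchanged; samples outside
#'   the common support are dropped.
#' @export
sig_intersect <- function(a, b) {
  if (abs(a$delta - b$delta) > time_tol(a$delta)) stop("delta mismatch")
  ia <- support_intervals(a); ib <- support_intervals(b)
  restrict <- function(x, iv) {
    if (n_samples(x) == 0L || nrow(iv) == 0L)
      return(seg_signal(numeric(0), numeric(0), integer(0), x$delta,
                        x$measurement, x$units, character(0), character(0)))
    tt <- sample_times(x)
    tol <- time_tol(x$delta)
    keep <- rep(FALSE, length(tt))
    for (k in seq_len(nrow(iv)))
      keep <- keep | (tt >= iv[k, 1] - tol & tt < iv[k, 2] - tol)
    if (!any(keep))
      return(seg_signal(numeric(0), numeric(0), integer(0), x$delta,
                        x$measurement, x$units, character(0), character(0)))
    build_segmented(tt[keep], x$data[keep], x$delta, x$measurement, x$units,
                    sample_sensors(x)[keep], sample_monitors(x)[keep])
  }
  list(a = restrict(a, ib), b = restrict(b, ia))
}

#' Concatenate segmented signals with non-overlapping supports
#'
#' Parts are merged in time order; adjacent parts that abut exactly (step of
#' one sampling increment across the join) fuse into a single segment.
#'
#' @param parts list of `seg_signal` objects with equal `delta` and pairwise
#'   disjoint time supports.
#' @return a single merged `seg_signal`.
#' @export
sig_concat <- function(parts) {
  parts <- parts[vapply(parts, n_samples, 1L) > 0L]
  if (length(parts) == 0L)
    return(seg_signal(numeric(0), numeric(0), integer(0)))
  delta <- parts[[1]]$delta
  for (p in parts)
    if (abs(p$delta - delta) > time_tol(delta)) stop("delta mismatch")
  ord <- order(vapply(parts, function(p) p$seg_start[1], 1))
  parts <- parts[ord]
  ends <- vapply(parts, function(p)
    p$seg_start[n_segments(p)] + p$seg_len[n_segments(p)] * p$delta, 1)
  starts <- vapply(parts, function(p) p$seg_start[1], 1)
  if (length(parts) > 1 &&
      any(starts[-1] < ends[-length(ends)] - time_tol(delta)))
    stop("overlap; use combine_sensors")
  tt <- unlist(lapply(parts, sample_times), use.names = FALSE)
  vv <- unlist(lapply(parts, function(p) p$data), use.names = FALSE)
  ss <- unlist(lapply(parts, sample_sensors), use.names = FALSE)
  mm <- unlist(lapply(parts, function(p) sample_monitors(p)),
               use.names = FALSE)
  p1 <- parts[[1]]
  build_segmented(tt, vv, delta, p1$measurement, p1$units, ss, mm)
}

#' EFM record: the signals of one tracing at one processing stage
#'
#' Container for the `seg_signal` objects belonging to one tracing.  At the
#' raw stage there may be several channels per measurement, keyed by
#' `measurement|sensor|monitor`; combined and repaired records hold at most
#' one signal per measurement (`FHR`, `UA`, `MHR`).
#'
#' @param guid opaque tracing identifier.
#' @param signals named list of `seg_signal` objects.
#' @param stage one of `"raw"`, `"combined"`, `"repaired"`.
#' @param provenance free-text source description.
#' @return an object of class `efm_record`.
#' @export
efm_record <- function(guid, signals, stage = c("raw", "combined", "repaired"),
                       provenance = "") {
  stage <- match.arg(stage)
  stopifnot(is.list(signals))
  deltas <- vapply(signals, function(s) s$delta, 1)
  if (length(deltas) > 1 && diff(range(deltas)) > time_tol(deltas[1]))
    stop("all signals in a record must share delta")
  if (stage != "raw") {
    meas <- vapply(signals, function(s) s$measurement, "")
    if (anyDuplicated(meas))
      stop("combined/repaired records hold at most one signal per measurement")
  }
  structure(list(guid = guid, stage = stage, signals = signals,
                 created = Sys.time(), provenance = provenance),
            class = "efm_record")
}

#' @export
print.efm_record <- function(x, ...) {
  cat(sprintf("<efm_record> %s (stage: %s)\n", x$guid, x$stage))
  for (nm in names(x$signals)) {
    s <- x$signals[[nm]]
    cat(sprintf("  %-28s %d seg, %d samples\n", nm, n_segments(s),
                n_samples(s)))
  }
  invisible(x)
}
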