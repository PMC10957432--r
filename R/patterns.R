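#' Pattern-detection configuration
#'
#' Numeric rules for the deterministic baseline/acceleration/deceleration/
#' contraction detectors.  The clinically fixed thresholds are the 15 bpm
#' excursion height and 15 s duration (both strict: "more than"), and the
#' 2-minute bound for prolonged decelerations; the remaining parameters
#' are documented conventions of this implementation.
#'
#' @param baseline_band half-width (bpm) of the band around the running
#'   baseline considered "at baseline" (default 10).
#' @param excursion_bpm strict height threshold for accelerations and
#'   decelerations, bpm (default 15).
#' @param excursion_s strict duration threshold, seconds (default 15).
#' @param prolonged_s minimum duration of a prolonged deceleration,
#'   seconds, inclusive (default 120).
#' @param abrupt_onset_s onset-to-nadir time below which a deceleration is
#'   abrupt (variable), seconds (default 30; standard clinical convention).
#' @param coincidence_tol_s tolerance (s) for deciding whether a gradual
#'   deceleration's nadir coincides with the paired contraction's peak
#'   (default 15).
#' @param baseline_window_s running-baseline window length, seconds
#'   (default 600, i.e. 10 min).
#' @param baseline_iter maximum baseline refinement iterations (default 5).
#' @param min_baseline_span_s minimum contiguous interpretable span (s)
#'   for which a baseline is estimated; shorter spans become RIN
#'   (default 120).
#' @param con_rise minimum rise of the smoothed uterine signal above
#'   resting tone, uncalibrated units (default 15).
#' @param con_min_s minimum contraction duration, seconds (default 30).
#' @param con_smooth_s uterine smoothing window, seconds (default 30).
#' @param resting_window_s window for the running resting-tone estimate,
#'   seconds (default 600).
#' @param resting_prob percentile defining resting tone (default 0.10).
#' @return a list of class `pattern_config`.
#' @export
pattern_config <- function(baseline_band = 10, excursion_bpm = 15,
                           excursion_s = 15, prolonged_s = 120,
                           abrupt_onset_s = 30, coincidence_tol_s = 15,
                           baseline_window_s = 600, baseline_iter = 5L,
                           min_baseline_span_s = 120,
                           con_rise = 15, con_min_s = 30,
                           con_smooth_s = 30, resting_window_s = 600,
                           resting_prob = 0.10) {
  structure(as.list(environment()), class = "pattern_config")
}

empty_events <- function() {
  data.frame(guid = character(0), type = character(0),
             start_s = numeric(0), end_s = numeric(0),
             level = numeric(0), variability = numeric(0),
             slope = numeric(0), height = numeric(0), area = numeric(0),
             subtype = character(0), nadir_s = numeric(0),
             onset_to_nadir_s = numeric(0), stringsAsFactors = FALSE)
}

event_row <- function(guid, type, start_s, end_s, level = NA_real_,
                      variability = NA_real_, slope = NA_real_,
                      height = NA_real_, area = NA_real_,
                      subtype = NA_character_, nadir_s = NA_real_,
                      onset_to_nadir_s = NA_real_) {
  data.frame(guid = guid, type = type, start_s = start_s, end_s = end_s,
             level = level, variability = variability, slope = slope,
             height = height, area = area, subtype = subtype,
             nadir_s = nadir_s, onset_to_nadir_s = onset_to_nadir_s,
             stringsAsFactors = FALSE)
}

# Rolling mean of x (NA-tolerant) over a centered window of w samples.
rolling_mean_masked <- function(x, keep, w) {
  n <- length(x)
  h <- floor(w / 2)
  xs <- c(0, cumsum(ifelse(keep, x, 0)))
  ns <- c(0, cumsum(as.numeric(keep)))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  s <- xs[hi + 1L] - xs[lo]
  m <- ns[hi + 1L] - ns[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  if (anyNA(out)) {
    fallback <- if (any(keep)) mean(x[keep]) else mean(x)
    out[is.na(out)] <- fallback
  }
  out
}

#' Estimate the running FHR baseline for one contiguous span
#'
#' The baseline is a 10-minute windowed mean that excludes candidate
#' excursion samples (those deviating more than the excursion threshold
#' from the current baseline), iterated to a fixed point from a running-
#' median start.  This keeps planted decelerations and accelerations from
#' dragging the estimate.
#'
#' @param x numeric FHR samples of one contiguous span.
#' @param delta sampling increment, seconds.
#' @param cfg a [pattern_config()].
#' @return numeric vector: the baseline value under every sample.
#' @export
estimate_baseline <- function(x, delta = 0.25, cfg = pattern_config()) {
  n <- length(x)
  w <- max(3L, round(cfg$baseline_window_s / delta))
  k <- min(if (w %% 2L == 1L) w else w + 1L,
           if (n %% 2L == 1L) n else n - 1L)
  b <- if (n >= 3L) stats::runmed(x, k, endrule = "median") else rep(median(x), n)
  for (it in seq_len(cfg$baseline_iter)) {
    keep <- abs(x - b) <= cfg$excursion_bpm
    b_new <- rolling_mean_masked(x, keep, w)
    if (max(abs(b_new - b)) < 0.25) { b <- b_new; break }
    b <- b_new
  }
  b
}

# Detect BAS/ACC/DEC/RIN partition of one contiguous interpretable span.
detect_fhr_span <- function(guid, tt, x, delta, cfg) {
  n <- length(x)
  span_start <- tt[1]; span_end <- tt[n] + delta
  if ((span_end - span_start) < cfg$min_baseline_span_s)
    return(event_row(guid, "RIN", span_start, span_end))
  b <- estimate_baseline(x, delta, cfg)
  dev <- x - b
  outside <- abs(dev) > cfg$baseline_band
  r <- rle(outside)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  ev <- empty_events()
  for (k in seq_along(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    t0 <- tt[i0]; t1 <- tt[i1] + delta
    if (!r$values[k]) {
      # at baseline: a BAS event
      seg <- x[i0:i1]
      tmin <- (tt[i0:i1] - tt[i0]) / 60
      slope <- if (length(seg) > 1) unname(coef(lm(seg ~ tmin))[2]) else 0
      detr <- seg - (if (length(seg) > 1) fitted(lm(seg ~ tmin)) else seg)
      ev <- rbind(ev, event_row(guid, "BAS", t0, t1,
                                level = mean(seg),
                                variability = diff(range(detr)),
                                slope = slope))
    } else {
      d <- dev[i0:i1]
      peak <- max(abs(d))
      dur <- (i1 - i0 + 1L) * delta
      is_acc <- mean(d) > 0
      qualifies <- peak > cfg$excursion_bpm + 1e-9 &&
        (dur > cfg$excursion_s + 1e-9)
      if (qualifies) {
        height <- peak
        area <- sum(abs(d)) * delta / 60   # beats
        if (is_acc) {
          ev <- rbind(ev, event_row(guid, "ACC", t0, t1, height = height,
                                    area = area))
        } else {
          nadir_i <- i0 + which.min(dev[i0:i1]) - 1L
          ev <- rbind(ev, event_row(guid, "DEC", t0, t1, height = height,
                                    area = area, nadir_s = tt[nadir_i],
                                    onset_to_nadir_s = tt[nadir_i] - t0))
        }
      } else {
        ev <- rbind(ev, event_row(guid, "RIN", t0, t1))
      }
    }
  }
  ev
}

#' Classify a deceleration into its clinical subtype
#'
#' Decelerations lasting at least two minutes are prolonged.  Abrupt
#' decelerations (onset-to-nadir under 30 s) are variable.  Gradual
#' decelerations are paired with the overlapping contraction: a nadir
#' within `coincidence_tol_s` of (or before) the contraction peak is
#' early; a nadir later than the peak by more than the tolerance is late;
#' a gradual deceleration with no paired contraction is variable.
#'
#' @param dec one-row deceleration event (needs `start_s`, `end_s`,
#'   `nadir_s`, `onset_to_nadir_s`).
#' @param contractions data.frame of CON events (columns `start_s`,
#'   `end_s`, `nadir_s` unused, `peak_s`).
#' @param cfg a [pattern_config()].
#' @return one of `"prolonged"`, `"variable"`, `"early"`, `"late"`.
#' @export
classify_deceleration <- function(dec, contractions = NULL,
                                  cfg = pattern_config()) {
  dur <- dec$end_s - dec$start_s
  if (dur >= cfg$prolonged_s - 1e-9) return("prolonged")
  if (!is.na(dec$onset_to_nadir_s) &&
      dec$onset_to_nadir_s < cfg$abrupt_onset_s) return("variable")
  if (is.null(contractions) || nrow(contractions) == 0L) return("variable")
  # nearest contraction overlapping the deceleration in time
  ov <- pmin(contractions$end_s, dec$end_s) -
    pmax(contractions$start_s, dec$start_s)
  if (all(ov <= 0)) return("variable")
  con <- contractions[which.max(ov), ]
  if (dec$nadir_s > con$peak_s + cfg$coincidence_tol_s) "late" else "early"
}

# Rolling low-percentile resting tone, evaluated on a coarse grid and
# interpolated back to the sample grid.
rolling_percentile <- function(x, tt, delta, window_s, prob, hop_s = 30) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  hop <- max(1L, round(hop_s / delta))
  h <- window_s / 2
  centers <- seq(1L, n, by = hop)
  vals <- vapply(centers, function(i) {
    sel <- tt >= tt[i] - h & tt <= tt[i] + h
    quantile(x[sel], prob, names = FALSE)
  }, 1)
  if (length(centers) == 1L) return(rep(vals, n))
  approx(tt[centers], vals, xout = tt, rule = 2)$y
}

#' Detect uterine contractions
#'
#' The uterine signal is smoothed with a 30 s moving average; resting tone
#' is a running 10-minute low percentile.  A contraction is a span where
#' the smoothed signal rises at least `con_rise` units above resting tone
#' for at least `con_min_s` seconds.  Height and area are measured on the
#' raw signal relative to resting tone, so smoothing does not attenuate
#' the reported amplitude.
#'
#' @param ua a `seg_signal` of uterine activity.
#' @param cfg a [pattern_config()].
#' @param guid tracing identifier stamped on the events.
#' @return data.frame of CON events with `height`, `area` and `peak_s`
#'   (time of the raw peak).
#' @export
detect_contractions <- function(ua, cfg = pattern_config(), guid = "") {
  out <- cbind(empty_events()[0, ], peak_s = numeric(0))
  if (is.null(ua) || n_samples(ua) == 0L) return(out)
  delta <- ua$delta
  op <- onset_pointers(ua)
  for (k in seq_len(n_segments(ua))) {
    idx <- op[k]:(op[k] + ua$seg_len[k] - 1L)
    x <- ua$data[idx]
    tt <- sample_times(ua)[idx]
    if (length(x) * delta < cfg$con_min_s) next
    w <- max(1L, round(cfg$con_smooth_s / delta))
    sm <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- x[is.na(sm)]
    rest <- rolling_percentile(sm, tt, delta, cfg$resting_window_s,
                               cfg$resting_prob)
    above <- sm - rest >= cfg$con_rise
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      if ((i1 - i0 + 1L) * delta < cfg$con_min_s) next
      peak_i <- i0 + which.max(x[i0:i1]) - 1L
      height <- x[peak_i] - rest[peak_i]
      area <- sum(pmax(x[i0:i1] - rest[i0:i1], 0)) * delta
      row <- event_row(guid, "CON", tt[i0], tt[i1] + delta,
                       height = height, area = area)
      row$peak_s <- tt[peak_i]
      out <- rbind(out, row)
    }
  }
  out
}

# Remove NOI spans from a signal's samples; returns kept logical index.
mask_noi <- function(tt, noi, delta) {
  keep <- rep(TRUE, length(tt))
  if (is.null(noi) || nrow(noi) == 0L) return(keep)
  for (k in seq_len(nrow(noi)))
    keep <- keep & !(tt >= noi$start_s[k] - time_tol(delta) &
                       tt < noi$end_s[k] - time_tol(delta))
  keep
}

#' Detect all CTG patterns in a repaired record
#'
#' Runs the rule-based detectors over the repaired FHR and UA: the
#' interpretable FHR timeline is partitioned into BAS, ACC, DEC and RIN
#' events; NOI intervals are carried through as events; contractions are
#' detected on the UA; deceleration subtypes are assigned using the
#' contraction pairing.
#'
#' @param record an `efm_record` at stage `"repaired"`.
#' @param noi NOI interval table as returned by [repair_record()].
#' @param cfg a [pattern_config()].
#' @return data.frame of events (BAS/ACC/DEC/RIN/NOI/CON) with attributes.
#' @export
detect_patterns <- function(record, noi = NULL, cfg = pattern_config()) {
  guid <- record$guid
  ev <- cbind(empty_events()[0, ], peak_s = numeric(0))
  cons <- detect_contractions(record$signals$UA, cfg, guid)
  fhr <- record$signals$FHR
  if (!is.null(fhr) && n_samples(fhr) > 0L) {
    delta <- fhr$delta
    tt <- sample_times(fhr)
    keep <- mask_noi(tt, noi, delta)
    if (any(keep)) {
      kt <- tt[keep]; kx <- fhr$data[keep]
      brk <- diff(kt) > delta + time_tol(delta)
      run_id <- cumsum(c(TRUE, brk))
      for (g in unique(run_id)) {
        sel <- run_id == g
        rows <- detect_fhr_span(guid, kt[sel], kx[sel], delta, cfg)
        if (nrow(rows)) {
          rows$peak_s <- NA_real_
          ev <- rbind(ev, rows)
        }
      }
    }
  }
  if (!is.null(noi) && nrow(noi)) {
    nr <- event_row(guid, "NOI", noi$start_s, noi$end_s)
    nr$peak_s <- NA_real_
    ev <- rbind(ev, nr)
  }
  if (nrow(cons)) ev <- rbind(ev, cons)
  # deceleration subtypes, paired against detected contractions
  dec_i <- which(ev$type == "DEC")
  for (i in dec_i)
    ev$subtype[i] <- classify_deceleration(ev[i, ], cons, cfg)
  ev <- ev[order(ev$start_s, ev$type), ]
  rownames(ev) <- NULL
  ev
}
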