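#' Repair configuration
#'
#' Parameters governing FHR gap repair and uninterpretability flagging.
#' The only externally fixed rule is the interpolation bound: only gaps
#' strictly shorter than 15 s are bridged by linear interpolation.  The
#' remaining heuristics (maternal-heart-rate capture, impulse noise,
#' physiologic range) stand in for a proprietary repair stage and are
#' fully configurable.
#'
#' @param max_interp_gap strict upper bound (s) on the duration of gaps
#'   bridged by linear interpolation; default 15.
#' @param dropout_value stored sample value marking a monitor dropout
#'   (default 0 bpm).
#' @param min_dropout_run minimum run length (samples) of dropout values
#'   converted to a gap; default 1 (every dropout sample).
#' @param mhr_coincidence_tol FHR-MHR agreement tolerance in bpm
#'   (default 5).
#' @param mhr_coincidence_min minimum continuous agreement (s) flagged as
#'   maternal-heart-rate capture (default 60).
#' @param noise_jump sample-to-sample change (bpm) counted as an impulse
#'   artifact (default 25).
#' @param physiologic_range plausible FHR range in bpm (default 50-240).
#' @return a list of class `repair_config`.
#' @export
repair_config <- function(max_interp_gap = 15, dropout_value = 0,
                          min_dropout_run = 1L, mhr_coincidence_tol = 5,
                          mhr_coincidence_min = 60, noise_jump = 25,
                          physiologic_range = c(50, 240)) {
  stopifnot(max_interp_gap > 0, min_dropout_run >= 1,
            mhr_coincidence_tol > 0, mhr_coincidence_min > 0,
            noise_jump > 0, length(physiologic_range) == 2)
  structure(list(max_interp_gap = max_interp_gap,
                 dropout_value = dropout_value,
                 min_dropout_run = as.integer(min_dropout_run),
                 mhr_coincidence_tol = mhr_coincidence_tol,
                 mhr_coincidence_min = mhr_coincidence_min,
                 noise_jump = noise_jump,
                 physiologic_range = physiologic_range),
            class = "repair_config")
}

#' Convert FHR dropout samples to gaps
#'
#' Monitors store a heart rate of zero when they cannot estimate the rate;
#' these dropout samples are removed, leaving gaps, so that the
#' interpolation stage can bridge the short ones.
#'
#' @param fhr a `seg_signal`.
#' @param cfg a [repair_config()].
#' @return the signal with dropout runs of at least `min_dropout_run`
#'   samples removed; other samples untouched.
#' @export
dropouts_to_gaps <- function(fhr, cfg = repair_config()) {
  if (n_samples(fhr) == 0L) return(fhr)
  is_drop <- fhr$data == cfg$dropout_value
  if (cfg$min_dropout_run > 1L) {
    r <- rle(is_drop)
    r$values <- r$values & r$lengths >= cfg$min_dropout_run
    is_drop <- inverse.rle(r)
  }
  if (!any(is_drop)) return(fhr)
  keep <- !is_drop
  if (!any(keep))
    return(seg_signal(numeric(0), numeric(0), integer(0), fhr$delta,
                      fhr$measurement, fhr$units, character(0),
                      character(0)))
  tt <- sample_times(fhr)
  build_segmented(tt[keep], fhr$data[keep], fhr$delta, fhr$measurement,
                  fhr$units, sample_sensors(fhr)[keep],
                  sample_monitors(fhr)[keep])
}

#' Bridge short FHR gaps by linear interpolation
#'
#' Every interior gap strictly shorter than `max_interp_gap` seconds is
#' filled with samples on the line between the flanking values; the
#' flanking segments then fuse.  Gaps at the signal boundary have no
#' flanks and are never interpolated.  Original sample values are never
#' modified.
#'
#' @inheritParams dropouts_to_gaps
#' @return the repaired `seg_signal`.
#' @export
interpolate_short_gaps <- function(fhr, cfg = repair_config()) {
  nseg <- n_segments(fhr)
  if (nseg <= 1L) return(fhr)
  gaps <- find_gaps(fhr)
  bridge <- gaps$duration < cfg$max_interp_gap - time_tol(fhr$delta)
  if (!any(bridge)) return(fhr)
  delta <- fhr$delta
  op <- onset_pointers(fhr)
  tt <- sample_times(fhr)
  new_t <- list(); new_v <- list(); new_s <- list(); new_m <- list()
  sens <- sample_sensors(fhr); mons <- sample_monitors(fhr)
  for (k in seq_len(nseg)) {
    idx <- op[k]:(op[k] + fhr$seg_len[k] - 1L)
    new_t[[length(new_t) + 1L]] <- tt[idx]
    new_v[[length(new_v) + 1L]] <- fhr$data[idx]
    new_s[[length(new_s) + 1L]] <- sens[idx]
    new_m[[length(new_m) + 1L]] <- mons[idx]
    if (k < nseg && bridge[k]) {
      i_prev <- op[k] + fhr$seg_len[k] - 1L  # last sample before the gap
      i_next <- op[k + 1L]                   # first sample after
      t_prev <- tt[i_prev]; t_next <- tt[i_next]
      nmiss <- round((t_next - t_prev) / delta) - 1L
      frac <- seq_len(nmiss) / (nmiss + 1L)
      new_t[[length(new_t) + 1L]] <- t_prev + seq_len(nmiss) * delta
      new_v[[length(new_v) + 1L]] <-
        fhr$data[i_prev] + (fhr$data[i_next] - fhr$data[i_prev]) * frac
      new_s[[length(new_s) + 1L]] <- rep("interpolated", nmiss)
      new_m[[length(new_m) + 1L]] <- rep(mons[i_prev], nmiss)
    }
  }
  build_segmented(unlist(new_t), unlist(new_v), delta, fhr$measurement,
                  fhr$units, unlist(new_s), unlist(new_m))
}

# Merge overlapping/adjacent half-open intervals; reasons are joined.
merge_intervals <- function(iv, join_tol) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(out)
    if (iv$start_s[k] <= out$end_s[last] + join_tol) {
      out$end_s[last] <- max(out$end_s[last], iv$end_s[k])
      rs <- unique(c(strsplit(out$reason[last], ",")[[1]], iv$reason[k]))
      out$reason[last] <- paste(rs, collapse = ",")
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}

# Runs of TRUE in a logical vector -> half-open time intervals.
runs_to_intervals <- function(flag, tt, delta, reason) {
  if (!any(flag)) return(data.frame(start_s = numeric(0),
                                    end_s = numeric(0),
                                    reason = character(0)))
  r <- rle(flag)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(start_s = tt[starts[sel]], end_s = tt[ends[sel]] + delta,
             reason = reason, stringsAsFactors = FALSE)
}

#' Flag uninterpretable FHR spans
#'
#' Marks NOI (noise/artifact) intervals where the signal cannot be read as
#' fetal heart rate: (a) the FHR tracks the maternal heart rate (absolute
#' difference below `mhr_coincidence_tol` continuously for at least
#' `mhr_coincidence_min` seconds), (b) impulse noise (three or more
#' sample-to-sample jumps above `noise_jump` bpm within 10 s), or (c)
#' values outside the physiologic range.  Flagged intervals are recorded
#' as events, not deleted, so downstream feature code can exclude them.
#'
#' @param fhr repaired FHR `seg_signal`.
#' @param mhr optional maternal heart rate `seg_signal`.
#' @param cfg a [repair_config()].
#' @return data.frame of merged NOI intervals: `start_s`, `end_s`,
#'   `reason`.
#' @export
flag_uninterpretable <- function(fhr, mhr = NULL, cfg = repair_config()) {
  delta <- fhr$delta
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      reason = character(0))
  if (n_samples(fhr) == 0L) return(empty)
  tt <- sample_times(fhr)
  iv <- empty

  # (c) out of physiologic range
  oor <- fhr$data < cfg$physiologic_range[1] |
    fhr$data > cfg$physiologic_range[2]
  iv <- rbind(iv, runs_to_intervals(oor, tt, delta, "range"))

  # (b) recurrent impulse noise: >=3 large jumps within 10 s
  jump_at <- abs(diff(fhr$data)) > cfg$noise_jump &
    diff(tt) < delta + time_tol(delta)
  jt <- tt[which(jump_at) + 1L]
  if (length(jt) >= 3L) {
    flagged <- rep(FALSE, length(tt))
    for (k in seq_len(length(jt) - 2L)) {
      if (jt[k + 2L] - jt[k] <= 10) {
        flagged <- flagged | (tt >= jt[k] - delta & tt <= jt[k + 2L])
      }
    }
    iv <- rbind(iv, runs_to_intervals(flagged, tt, delta, "noise"))
  }

  # (a) maternal heart rate capture
  if (!is.null(mhr) && n_samples(mhr) > 0L) {
    common <- sig_intersect(fhr, mhr)
    fa <- common$a; mb <- common$b
    if (n_samples(fa) > 0L) {
      ta <- sample_times(fa)
      close <- abs(fa$data - mb$data) < cfg$mhr_coincidence_tol
      # break agreement runs across gaps
      gap_after <- c(diff(ta) > fa$delta + time_tol(delta), TRUE)
      r <- rle(close)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        # split at internal gaps
        seg_brk <- which(gap_after[starts[k]:(ends[k] - 1L)]) + starts[k] - 1L
        bounds <- c(starts[k] - 1L, seg_brk, ends[k])
        for (j in seq_len(length(bounds) - 1L)) {
          i0 <- bounds[j] + 1L; i1 <- bounds[j + 1L]
          dur <- ta[i1] - ta[i0] + delta
          if (dur >= cfg$mhr_coincidence_min)
            iv <- rbind(iv, data.frame(start_s = ta[i0],
                                       end_s = ta[i1] + delta,
                                       reason = "mhr_capture"))
        }
      }
    }
  }
  merge_intervals(iv, join_tol = delta + time_tol(delta))
}

#' Repair a combined EFM record
#'
#' Applies the full Stage-6 analogue to a combined record: FHR dropouts
#' become gaps, short gaps are bridged by linear interpolation, and
#' uninterpretable spans are flagged.  Uterine activity is never
#' interpolated; UA and MHR pass through unchanged.
#'
#' @param combined an `efm_record` at stage `"combined"`.
#' @param cfg a [repair_config()].
#' @return a list: `record` (stage `"repaired"`) and `noi` (the NOI
#'   interval table with a `guid` column).
#' @export
repair_record <- function(combined, cfg = repair_config()) {
  sigs <- combined$signals
  noi <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    reason = character(0))
  if ("FHR" %in% names(sigs)) {
    fhr <- dropouts_to_gaps(sigs$FHR, cfg)
    fhr <- interpolate_short_gaps(fhr, cfg)
    sigs$FHR <- fhr
    noi <- flag_uninterpretable(fhr, sigs$MHR, cfg)
  }
  rec <- efm_record(combined$guid, sigs, stage = "repaired",
                    provenance = combined$provenance)
  if (nrow(noi)) noi <- cbind(guid = combined$guid, noi)
  else noi <- data.frame(guid = character(0), start_s = numeric(0),
                         end_s = numeric(0), reason = character(0))
  list(record = rec, noi = noi)
}
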