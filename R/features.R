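#' Feature-extraction configuration
#'
#' Epoch geometry and the parameters of the variability battery.  The
#' defaults are the stated analysis conditions: non-overlapping 20-minute
#' epochs retained only when at least 80 % of their samples (3840 at
#' 4 Hz) remain interpretable; a 30 mHz split between slow-trend and
#' variability components; Lomb-Scargle bands LF 30-150 mHz, MF
#' 150-500 mHz, HF 0.5-1 Hz; phase-rectified signal averaging with
#' T = 2.5 s and L = 25 s; entropies with m = 2 and r in
#' (0.1, 0.2, 0.3) x SD; a 2.5 s grid for the classical variability
#' indices; and embedding dimension 2 with delay 1 for the nonlinear
#' measures.
#'
#' @param epoch_s epoch length in seconds (default 1200).
#' @param min_coverage minimum interpretable fraction for epoch retention
#'   (default 0.80).
#' @param split_hz low/high component split frequency, Hz (default 0.030).
#' @param band_edges named list of Lomb-Scargle band edges in Hz.
#' @param prsa_T PRSA time-scale parameter, seconds (default 2.5).
#' @param prsa_L PRSA averaging half-window, seconds (default 25).
#' @param entropy_m embedding dimension for ApEn/SampEn (default 2).
#' @param entropy_r similarity tolerances as fractions of SD.
#' @param stv_step grid step for classical variability, seconds (2.5).
#' @param delta_window window for the Delta index, seconds (default 60).
#' @param embed_dim,embed_delay embedding for Lyapunov and correlation
#'   dimension (defaults 2 and 1).
#' @param adjacency_s maximum separation (s) between consecutive FHR
#'   events still counted as a transition (default 30).
#' @return a list of class `feature_config`.
#' @export
feature_config <- function(epoch_s = 1200, min_coverage = 0.80,
                           split_hz = 0.030,
                           band_edges = list(LF = c(0.030, 0.150),
                                             MF = c(0.150, 0.500),
                                             HF = c(0.5, 1.0)),
                           prsa_T = 2.5, prsa_L = 25,
                           entropy_m = 2L, entropy_r = c(0.1, 0.2, 0.3),
                           stv_step = 2.5, delta_window = 60,
                           embed_dim = 2L, embed_delay = 1L,
                           adjacency_s = 30) {
  structure(as.list(environment()), class = "feature_config")
}

#' Tile a record into 20-minute epochs and decide retention
#'
#' Epochs tile backwards from birth (time 0) in non-overlapping blocks.
#' NOI samples are discarded; an epoch is retained only if the remaining
#' FHR samples number at least `min_coverage * epoch_s / delta`
#' (3840 at the defaults).
#'
#' @param record a repaired `efm_record`.
#' @param noi NOI interval table.
#' @param cfg a [feature_config()].
#' @return data.frame: `epoch_index` (0 = the epoch ending at birth),
#'   `start_s`, `end_s`, `n_interpretable`, `interpretable_fraction`,
#'   `retained`.
#' @export
segment_epochs <- function(record, noi = NULL, cfg = feature_config()) {
  fhr <- record$signals$FHR
  out <- data.frame(epoch_index = integer(0), start_s = numeric(0),
                    end_s = numeric(0), n_interpretable = integer(0),
                    interpretable_fraction = numeric(0),
                    retained = logical(0))
  if (is.null(fhr) || n_samples(fhr) == 0L) return(out)
  delta <- fhr$delta
  tt <- sample_times(fhr)
  keep <- mask_noi(tt, noi, delta)
  kt <- tt[keep]
  first_epoch <- floor(-min(tt) / cfg$epoch_s - 1e-9)
  n_full <- cfg$epoch_s / delta
  min_n <- ceiling(cfg$min_coverage * n_full)
  rows <- lapply(first_epoch:0, function(k) {
    e_start <- -(k + 1) * cfg$epoch_s
    e_end <- -k * cfg$epoch_s
    n_in <- sum(kt >= e_start - time_tol(delta) &
                  kt < e_end - time_tol(delta))
    data.frame(epoch_index = k, start_s = e_start, end_s = e_end,
               n_interpretable = n_in,
               interpretable_fraction = n_in / n_full,
               retained = n_in >= min_n)
  })
  do.call(rbind, rows)
}

#' Sequential (marked-point-process) features for one epoch
#'
#' Dwell times per event type within the epoch, transition counts between
#' FHR events, cumulative dwell from monitoring start to the epoch start,
#' contraction rate per 10 minutes, and deceleration subtype frequencies
#' grouped as late / abrupt (= variable) / others (= early + prolonged).
#'
#' @param events full event table for the tracing.
#' @param epoch_start,epoch_end epoch bounds in seconds.
#' @param cfg a [feature_config()].
#' @return a one-row data.frame of sequential features.
#' @export
sequential_features <- function(events, epoch_start, epoch_end,
                                cfg = feature_config()) {
  types <- c("BAS", "ACC", "DEC", "CON", "RIN", "NOI")
  clip <- function(ev) {
    s <- pmax(ev$start_s, epoch_start); e <- pmin(ev$end_s, epoch_end)
    pmax(e - s, 0)
  }
  dwell <- vapply(types, function(ty) {
    ev <- events[events$type == ty, , drop = FALSE]
    if (nrow(ev) == 0L) 0 else sum(clip(ev))
  }, 1)
  cumdwell <- vapply(types, function(ty) {
    ev <- events[events$type == ty, , drop = FALSE]
    if (nrow(ev) == 0L) return(0)
    s <- ev$start_s; e <- pmin(ev$end_s, epoch_start)
    sum(pmax(e - s, 0))
  }, 1)
  # transitions among FHR events in time order; events separated by more
  # than adjacency_s (long unclassified spans, long gaps) are not adjacent
  fhr_ev <- events[events$type %in% c("BAS", "ACC", "DEC") &
                     events$end_s > epoch_start &
                     events$start_s < epoch_end, , drop = FALSE]
  fhr_ev <- fhr_ev[order(fhr_ev$start_s), , drop = FALSE]
  trans <- matrix(0L, 3, 3,
                  dimnames = list(c("BAS", "ACC", "DEC"),
                                  c("BAS", "ACC", "DEC")))
  if (nrow(fhr_ev) > 1L) {
    for (i in seq_len(nrow(fhr_ev) - 1L)) {
      gap <- fhr_ev$start_s[i + 1L] - fhr_ev$end_s[i]
      if (gap <= cfg$adjacency_s)
        trans[fhr_ev$type[i], fhr_ev$type[i + 1L]] <-
          trans[fhr_ev$type[i], fhr_ev$type[i + 1L]] + 1L
    }
  }
  cons <- events[events$type == "CON", , drop = FALSE]
  con_mid <- if (nrow(cons)) {
    p <- cons$peak_s
    p[is.na(p)] <- (cons$start_s[is.na(p)] + cons$end_s[is.na(p)]) / 2
    p
  } else numeric(0)
  n_con <- sum(con_mid >= epoch_start & con_mid < epoch_end)
  con_rate <- n_con / (( epoch_end - epoch_start) / 600)
  decs <- events[events$type == "DEC", , drop = FALSE]
  dec_mid <- if (nrow(decs)) {
    p <- decs$nadir_s
    p[is.na(p)] <- (decs$start_s[is.na(p)] + decs$end_s[is.na(p)]) / 2
    p
  } else numeric(0)
  in_ep <- dec_mid >= epoch_start & dec_mid < epoch_end
  sub <- decs$subtype[in_ep]
  out <- data.frame(
    dwell_BAS = dwell["BAS"], dwell_ACC = dwell["ACC"],
    dwell_DEC = dwell["DEC"], dwell_CON = dwell["CON"],
    dwell_RIN = dwell["RIN"], dwell_NOI = dwell["NOI"],
    cumdwell_BAS = cumdwell["BAS"], cumdwell_ACC = cumdwell["ACC"],
    cumdwell_DEC = cumdwell["DEC"], cumdwell_CON = cumdwell["CON"],
    cumdwell_RIN = cumdwell["RIN"], cumdwell_NOI = cumdwell["NOI"],
    con_rate_per10min = con_rate,
    dec_late = sum(sub == "late"),
    dec_abrupt = sum(sub == "variable"),
    dec_others = sum(sub %in% c("early", "prolonged")),
    row.names = NULL)
  for (a in rownames(trans)) for (b in colnames(trans))
    out[[paste0("trans_", a, "_", b)]] <- trans[a, b]
  out
}

#' Split a signal into low- and high-frequency components
#'
#' Fourier transform, zero the bins outside the band, inverse transform.
#' Every bin is assigned to exactly one component (low: |f| at or below
#' `split_hz`), so the two components sum to the original signal to
#' numerical precision.
#'
#' @param x numeric samples (treated as contiguous).
#' @param delta sampling increment, seconds.
#' @param split_hz split frequency, Hz.
#' @return list with numeric components `low` and `high`.
#' @export
decompose_spectral <- function(x, delta = 0.25, split_hz = 0.030) {
  n <- length(x)
  if (n < 2L) return(list(low = x, high = rep(0, length(x))))
  X <- fft(x)
  k <- 0:(n - 1)
  f <- ifelse(k <= n / 2, k, k - n) / (n * delta)
  low_mask <- abs(f) <= split_hz + 1e-12
  low <- Re(fft(X * low_mask, inverse = TRUE)) / n
  high <- Re(fft(X * !low_mask, inverse = TRUE)) / n
  list(low = low, high = high)
}

#' Phase-rectified signal averaging
#'
#' Anchors are points where the mean over the next `T` seconds exceeds
#' (increment anchors, acceleration capacity) or falls below (decrement
#' anchors, deceleration capacity) the mean over the preceding `T`
#' seconds.  Windows of +/- `L` seconds around all anchors are aligned
#' and averaged, and the capacity is the Haar-wavelet quantifier at scale
#' `T`: the mean of the two T-blocks after the anchor minus the two
#' before, divided by four.
#'
#' @param x numeric samples.
#' @param delta sampling increment, seconds.
#' @param anchors `"increment"` (AC) or `"decrement"` (DC).
#' @param T_s time-scale parameter in seconds (default 2.5).
#' @param L_s averaging half-window in seconds (default 25).
#' @return list: `value` (the capacity, `NA` when no anchors),
#'   `n_anchors`, and `profile` (the averaged window).
#' @export
prsa <- function(x, delta = 0.25, anchors = c("increment", "decrement"),
                 T_s = 2.5, L_s = 25) {
  anchors <- match.arg(anchors)
  n <- length(x)
  Tn <- max(1L, round(T_s / delta))
  Ln <- max(2L * Tn, round(L_s / delta))
  if (n < 2L * Ln + 1L)
    return(list(value = NA_real_, n_anchors = 0L, profile = NULL))
  cs <- c(0, cumsum(x))
  i <- (Ln + 1L):(n - Ln)
  after <- (cs[i + Tn] - cs[i]) / Tn          # mean x[i .. i+Tn-1]
  before <- (cs[i] - cs[i - Tn]) / Tn         # mean x[i-Tn .. i-1]
  sel <- if (anchors == "increment") after > before else after < before
  anchor_idx <- i[sel]
  if (length(anchor_idx) == 0L)
    return(list(value = NA_real_, n_anchors = 0L, profile = NULL))
  offs <- (-Ln):(Ln - 1L)
  prof <- vapply(offs, function(o) mean(x[anchor_idx + o]), 1)
  names(prof) <- offs
  block <- function(o0) mean(prof[as.character(o0:(o0 + Tn - 1L))])
  value <- (block(0L) + block(Tn) - block(-Tn) - block(-2L * Tn)) / 4
  list(value = value, n_anchors = length(anchor_idx), profile = prof)
}

#' @rdname prsa
#' @details `prsa_features()` returns acceleration capacity (AC,
#'   increment anchors), deceleration capacity (DC, decrement anchors)
#'   and the deceleration reserve DR = DC - AC.
#' @export
prsa_features <- function(x, delta = 0.25, T_s = 2.5, L_s = 25) {
  ac <- prsa(x, delta, "increment", T_s, L_s)$value
  dc <- prsa(x, delta, "decrement", T_s, L_s)$value
  c(AC = ac, DC = dc, DR = dc - ac)
}

#' Lomb-Scargle periodogram
#'
#' Classical normalized Lomb-Scargle periodogram for unevenly sampled
#' data, evaluated at the supplied frequencies.  Gaps in the sampling are
#' handled without interpolation: the estimate uses the actual sample
#' times.
#'
#' @param t sample times, seconds.
#' @param x sample values.
#' @param freq frequencies in Hz at which to evaluate.
#' @return numeric vector of normalized power at each frequency.
#' @export
lomb_scargle <- function(t, x, freq) {
  x <- x - mean(x)
  s2 <- var(x)
  if (!is.finite(s2) || s2 <= 0) return(rep(NA_real_, length(freq)))
  out <- numeric(length(freq))
  block <- 256L
  for (i0 in seq(1L, length(freq), by = block)) {
    i1 <- min(i0 + block - 1L, length(freq))
    w <- 2 * pi * freq[i0:i1]
    wt <- outer(t, w)                       # n x nf
    s2wt <- sin(2 * wt); c2wt <- cos(2 * wt)
    tau <- atan2(colSums(s2wt), colSums(c2wt)) / (2 * w)
    ph <- wt - rep(w * tau, each = length(t))
    ct <- cos(ph); st <- sin(ph)
    out[i0:i1] <- (colSums(x * ct)^2 / colSums(ct^2) +
                     colSums(x * st)^2 / colSums(st^2)) / (2 * s2)
  }
  out
}

#' Spectral band powers from the Lomb-Scargle periodogram
#'
#' Integrates the periodogram over the fetal heart rate assessment bands
#' (LF 30-150 mHz, MF 150-500 mHz, HF 0.5-1 Hz by default), normalizes
#' by the signal variance, and forms the LF/(MF+HF) ratio.
#'
#' @param t sample times (seconds; gaps allowed).
#' @param x sample values.
#' @param cfg a [feature_config()].
#' @return named vector `LF`, `MF`, `HF` (normalized band powers) and
#'   `LF_MF_HF_ratio`.
#' @export
lomb_bands <- function(t, x, cfg = feature_config()) {
  out <- c(LF = NA_real_, MF = NA_real_, HF = NA_real_,
           LF_MF_HF_ratio = NA_real_)
  if (length(t) < 8L) return(out)
  span <- diff(range(t))
  if (span < 60 || var(x) <= 0) return(out)
  df <- 1 / span   # natural Rayleigh-resolution frequency grid
  pow <- vapply(names(cfg$band_edges), function(bn) {
    e <- cfg$band_edges[[bn]]
    freq <- seq(max(e[1], df), e[2], by = df)
    p <- lomb_scargle(t, x, freq)
    sum(p) * df   # integrated normalized power
  }, 1)
  out["LF"] <- pow["LF"]; out["MF"] <- pow["MF"]; out["HF"] <- pow["HF"]
  out["LF_MF_HF_ratio"] <- pow["LF"] / (pow["MF"] + pow["HF"])
  out
}

# Chebyshev template counting for ApEn/SampEn (compiled; O(n^2)).
entropy_counts <- function(x, m, r_vec) {
  out <- .cheb_counts(as.numeric(x), as.integer(m), as.numeric(r_vec))
  out$n <- length(x); out$m <- m
  out
}

#' Approximate and sample entropy
#'
#' Standard definitions with Chebyshev distance: ApEn counts
#' self-matches; SampEn does not.  The tolerance values are fractions of
#' the analyzed segment's standard deviation.  A constant signal is
#' perfectly regular: both entropies are defined as 0 and flagged
#' degenerate.
#'
#' @param x numeric samples (at least 100 recommended).
#' @param m embedding dimension (default 2).
#' @param r_frac tolerance fractions of SD (default 0.1, 0.2, 0.3).
#' @return data.frame with columns `r`, `ApEn`, `SampEn`, `degenerate`.
#' @export
entropies <- function(x, m = 2L, r_frac = c(0.1, 0.2, 0.3)) {
  s <- sd(x)
  if (!is.finite(s) || s == 0 || length(x) < m + 2L)
    return(data.frame(r = r_frac, ApEn = 0, SampEn = 0, degenerate = TRUE))
  cnt <- entropy_counts(x, m, r_frac * s)
  n <- cnt$n
  apen <- vapply(seq_along(r_frac), function(ri) {
    c_m <- cnt$phi_m[, ri] / (n - m + 1L)
    c_m1 <- cnt$phi_m1[, ri] / (n - m)
    mean(log(c_m)) - mean(log(c_m1))
  }, 1)
  sampen <- vapply(seq_along(r_frac), function(ri) {
    if (cnt$B[ri] <= 0 || cnt$A[ri] <= 0) return(NA_real_)
    -log(cnt$A[ri] / cnt$B[ri])
  }, 1)
  data.frame(r = r_frac, ApEn = apen, SampEn = sampen, degenerate = FALSE)
}

#' Hurst exponent by rescaled-range analysis
#'
#' R/S statistics over dyadic window sizes, with the exponent obtained
#' from the slope of log(R/S) against log(window size).
#'
#' @param x numeric samples (at least 256 recommended).
#' @param min_window smallest window size (default 16).
#' @return the estimated Hurst exponent, or `NA` for degenerate input.
#' @export
hurst_rs <- function(x, min_window = 16L) {
  n <- length(x)
  if (n < 2L * min_window || sd(x) == 0) return(NA_real_)
  sizes <- c()
  s <- min_window
  while (s <= n / 2) { sizes <- c(sizes, s); s <- s * 2L }
  rs <- vapply(sizes, function(w) {
    nb <- floor(n / w)
    vals <- vapply(seq_len(nb), function(b) {
      seg <- x[((b - 1L) * w + 1L):(b * w)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      s <- sd(seg)
      if (s == 0) NA_real_ else r / s
    }, 1)
    mean(vals, na.rm = TRUE)
  }, 1)
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 2L) return(NA_real_)
  unname(coef(lm(log(rs[ok]) ~ log(sizes[ok])))[2])
}

# Delay embedding (dimension m, delay d) as an (n - (m-1)d) x m matrix.
embed_delay <- function(x, m, d) {
  n <- length(x) - (m - 1L) * d
  sapply(seq_len(m), function(j) x[(seq_len(n)) + (j - 1L) * d])
}

#' Largest Lyapunov exponent (Rosenstein method)
#'
#' Embeds the signal (dimension 2, delay 1 by default), tracks the mean
#' log-divergence of nearest-neighbor trajectory pairs, and fits the
#' initial slope.  Positive values indicate sensitive dependence on
#' initial conditions.
#'
#' @param x numeric samples.
#' @param delta sampling increment, seconds.
#' @param m,d embedding dimension and delay.
#' @param min_sep minimum temporal separation of neighbor pairs, samples.
#' @param k_max divergence horizon, samples.
#' @return estimated exponent in 1/s, or `NA` for degenerate input.
#' @export
lyapunov_exponent <- function(x, delta = 0.25, m = 2L, d = 1L,
                              min_sep = 10L, k_max = 20L,
                              max_points = 1200L) {
  if (length(x) < 64L || sd(x) == 0) return(NA_real_)
  Y <- embed_delay(x, m, d)
  M <- nrow(Y) - k_max
  if (M < min_sep + 2L) return(NA_real_)
  # deterministic thinning of trajectory/neighbor candidates keeps the
  # pairwise search bounded; divergence is tracked on the full series
  cand <- if (M > max_points)
    unique(round(seq(1L, M, length.out = max_points))) else seq_len(M)
  logd <- matrix(NA_real_, length(cand), k_max + 1L)
  Yc <- Y[cand, , drop = FALSE]
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    dist0 <- sqrt(rowSums((Yc - matrix(Y[i, ], nrow(Yc), m,
                                       byrow = TRUE))^2))
    dist0[abs(cand - i) < min_sep] <- Inf
    jj <- which.min(dist0)
    if (!is.finite(dist0[jj])) next
    j <- cand[jj]
    for (k in 0:k_max) {
      dk <- sqrt(sum((Y[i + k, ] - Y[j + k, ])^2))
      if (dk > 0) logd[ii, k + 1L] <- log(dk)
    }
  }
  md <- colMeans(logd, na.rm = TRUE)
  ks <- (0:k_max) * delta
  ok <- is.finite(md)
  if (sum(ok) < 3L) return(NA_real_)
  unname(coef(lm(md[ok] ~ ks[ok]))[2])
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Correlation sums over log-spaced radii in the embedded space
#' (dimension 2, delay 1 by default); the dimension is the slope of
#' log C(r) against log r over the scaling range.  Long inputs are
#' deterministically thinned to bound the pairwise computation.
#'
#' @param x numeric samples.
#' @param m,d embedding dimension and delay.
#' @param max_points maximum embedded points used (default 1000).
#' @return estimated correlation dimension, or `NA` for degenerate input.
#' @export
correlation_dimension <- function(x, m = 2L, d = 1L, max_points = 1000L) {
  if (length(x) < 64L || sd(x) == 0) return(NA_real_)
  Y <- embed_delay(x, m, d)
  if (nrow(Y) > max_points) {
    idx <- round(seq(1L, nrow(Y), length.out = max_points))
    Y <- Y[idx, , drop = FALSE]
  }
  dm <- as.matrix(stats::dist(Y))
  dv <- dm[upper.tri(dm)]
  dv <- dv[dv > 0]
  if (length(dv) < 100L) return(NA_real_)
  rr <- exp(seq(log(quantile(dv, 0.05)), log(quantile(dv, 0.5)),
                length.out = 10))
  C <- vapply(rr, function(r) mean(dv <= r), 1)
  ok <- C > 0
  if (sum(ok) < 3L) return(NA_real_)
  unname(coef(lm(log(C[ok]) ~ log(rr[ok])))[2])
}

#' Classical variability indices on the 2.5-second grid
#'
#' STV: mean absolute difference of samples 2.5 s apart.  Delta: mean
#' peak-to-peak (max - min) range over one-minute windows.  Interval
#' index: STV divided by the SD of the 2.5 s grid samples.  Long-term
#' irregularity: interquartile range of the moduli
#' sqrt(s_j^2 + s_{j+1}^2) of consecutive grid samples.
#'
#' @param x numeric samples.
#' @param delta sampling increment, seconds.
#' @param cfg a [feature_config()].
#' @return named vector `STV`, `LTI`, `Delta`, `II`.
#' @export
classical_variability <- function(x, delta = 0.25, cfg = feature_config()) {
  out <- c(STV = NA_real_, LTI = NA_real_, Delta = NA_real_,
           II = NA_real_)
  step <- max(1L, round(cfg$stv_step / delta))
  if (length(x) < step + 1L) return(out)
  g <- x[seq(1L, length(x), by = step)]
  if (length(g) >= 2L) {
    out["STV"] <- mean(abs(diff(g)))
    mods <- sqrt(g[-length(g)]^2 + g[-1L]^2)
    out["LTI"] <- unname(diff(quantile(mods, c(0.25, 0.75))))
    sg <- sd(g)
    out["II"] <- if (sg > 0) out[["STV"]] / sg else NA_real_
  }
  wn <- round(cfg$delta_window / delta)
  nw <- floor(length(x) / wn)
  if (nw >= 1L) {
    rng <- vapply(seq_len(nw), function(b) {
      seg <- x[((b - 1L) * wn + 1L):(b * wn)]
      max(seg) - min(seg)
    }, 1)
    out["Delta"] <- mean(rng)
  }
  out
}

#' Default feature-cell mask
#'
#' Which feature is computed for which event type and spectral band:
#' mean/SD everywhere; slope only on the BAS slow component; height/area
#' on the ACC/DEC slow components; the PRSA, band-power, entropy,
#' fractal and classical-variability battery on the variability
#' (high-frequency) components of all three event types.  Pass an edited
#' copy to [assemble_feature_matrix()] to add or drop cells.
#'
#' @return data.frame with columns `feature`, `event`, `band`.
#' @export
default_ctg_feature_mask <- function() {
  hi_feats <- c("AC", "DC", "DR", "LF", "MF", "HF", "LF_MF_HF_ratio",
                "ApEn_0.1", "ApEn_0.2", "ApEn_0.3",
                "SampEn_0.1", "SampEn_0.2", "SampEn_0.3",
                "hurst", "lyapunov", "corr_dim",
                "STV", "LTI", "Delta", "II")
  rbind(
    expand.grid(feature = c("mean", "sd"), event = c("BAS", "ACC", "DEC"),
                band = c("low", "high"), stringsAsFactors = FALSE),
    data.frame(feature = "slope", event = "BAS", band = "low"),
    expand.grid(feature = c("height", "area"), event = c("ACC", "DEC"),
                band = "low", stringsAsFactors = FALSE),
    expand.grid(feature = hi_feats, event = c("BAS", "ACC", "DEC"),
                band = "high", stringsAsFactors = FALSE))
}

# Which event type covers each sample time (BAS/ACC/DEC, else NA).
event_type_at <- function(tt, events, delta) {
  out <- rep(NA_character_, length(tt))
  ev <- events[events$type %in% c("BAS", "ACC", "DEC"), , drop = FALSE]
  for (k in seq_len(nrow(ev))) {
    sel <- tt >= ev$start_s[k] - time_tol(delta) &
      tt < ev$end_s[k] - time_tol(delta)
    out[sel] <- ev$type[k]
  }
  out
}

#' Variability feature matrix for one epoch
#'
#' Decomposes the epoch's interpretable FHR samples into slow-trend
#' (below 30 mHz) and variability (above) components, masks each by the
#' event type covering it, and evaluates the feature battery on the cells
#' selected by the feature mask.  Cells with too few samples are `NA`.
#'
#' @param tt sample times of the epoch's interpretable FHR samples.
#' @param x the corresponding FHR values.
#' @param events event table for the tracing.
#' @param delta sampling increment, seconds.
#' @param cfg a [feature_config()].
#' @param mask cell mask (data.frame feature/event/band); default
#'   `default_ctg_feature_mask()`.
#' @return a one-row data.frame with columns `<feature>__<event>__<band>`.
#' @export
assemble_feature_matrix <- function(tt, x, events, delta = 0.25,
                                    cfg = feature_config(),
                                    mask = default_ctg_feature_mask()) {
  comp <- decompose_spectral(x, delta, cfg$split_hz)
  etype <- event_type_at(tt, events, delta)
  bas_low_mean <- if (any(etype == "BAS", na.rm = TRUE))
    mean(comp$low[which(etype == "BAS")]) else mean(comp$low)
  out <- list()
  for (ev in c("BAS", "ACC", "DEC")) {
    sel <- which(!is.na(etype) & etype == ev)
    for (band in c("low", "high")) {
      cells <- mask[mask$event == ev & mask$band == band, "feature"]
      if (length(cells) == 0L) next
      xs <- comp[[band]][sel]
      ts <- tt[sel]
      nxs <- length(xs)
      # expensive groups computed at most once per cell set
      prsa_v <- NULL; lomb_v <- NULL; cv_v <- NULL; ent_v <- NULL
      if (any(cells %in% c("AC", "DC", "DR")) && nxs > 0L)
        prsa_v <- prsa_features(xs, delta, cfg$prsa_T, cfg$prsa_L)
      if (any(cells %in% c("LF", "MF", "HF", "LF_MF_HF_ratio")) && nxs > 0L)
        lomb_v <- lomb_bands(ts, xs, cfg)
      if (any(cells %in% c("STV", "LTI", "Delta", "II")) && nxs > 0L)
        cv_v <- classical_variability(xs, delta, cfg)
      if (any(grepl("^(ApEn|SampEn)_", cells)) && nxs >= 100L)
        ent_v <- entropies(xs, cfg$entropy_m, cfg$entropy_r)
      for (feat in cells) {
        v <- if (nxs == 0L) NA_real_
        else if (feat == "mean") mean(xs)
        else if (feat == "sd") sd(xs)
        else if (feat == "slope") {
          if (nxs > 1L) unname(coef(lm(xs ~ I(ts / 60)))[2]) else NA_real_
        } else if (feat == "height") {
          d <- xs - bas_low_mean
          if (ev == "ACC") max(d) else min(d)
        } else if (feat == "area") {
          sum(abs(xs - bas_low_mean)) * delta / 60
        } else if (feat %in% c("AC", "DC", "DR")) {
          prsa_v[[feat]]
        } else if (feat %in% c("LF", "MF", "HF", "LF_MF_HF_ratio")) {
          lomb_v[[feat]]
        } else if (feat == "hurst") {
          if (nxs >= 256L) hurst_rs(xs) else NA_real_
        } else if (feat == "lyapunov") {
          lyapunov_exponent(xs, delta, cfg$embed_dim, cfg$embed_delay)
        } else if (feat == "corr_dim") {
          correlation_dimension(xs, cfg$embed_dim, cfg$embed_delay)
        } else if (feat %in% c("STV", "LTI", "Delta", "II")) {
          cv_v[[feat]]
        } else {
          parts <- strsplit(feat, "_")[[1]]
          if (is.null(ent_v)) NA_real_
          else {
            ri <- match(as.numeric(parts[2]), ent_v$r)
            if (parts[1] == "ApEn") ent_v$ApEn[ri] else ent_v$SampEn[ri]
          }
        }
        out[[paste(feat, ev, band, sep = "__")]] <- v
      }
    }
  }
  as.data.frame(out)
}

#' Extract the full per-epoch feature table for a tracing
#'
#' Segments the repaired record into epochs, drops non-retained epochs,
#' and computes the sequential and variability batteries for each
#' retained epoch.  Within an epoch the interpretable samples are
#' concatenated for time-domain features but keep their true timestamps
#' for the Lomb-Scargle spectral estimates.
#'
#' @param record a repaired `efm_record`.
#' @param events event table from [detect_patterns()].
#' @param noi NOI interval table.
#' @param cfg a [feature_config()].
#' @return data.frame: one row per retained epoch.
#' @export
extract_features <- function(record, events, noi = NULL,
                             cfg = feature_config()) {
  eps <- segment_epochs(record, noi, cfg)
  eps <- eps[eps$retained, , drop = FALSE]
  if (nrow(eps) == 0L) return(data.frame())
  fhr <- record$signals$FHR
  delta <- fhr$delta
  tt <- sample_times(fhr)
  keep <- mask_noi(tt, noi, delta)
  rows <- lapply(seq_len(nrow(eps)), function(i) {
    e <- eps[i, ]
    sel <- keep & tt >= e$start_s - time_tol(delta) &
      tt < e$end_s - time_tol(delta)
    seqf <- sequential_features(events, e$start_s, e$end_s, cfg)
    varf <- assemble_feature_matrix(tt[sel], fhr$data[sel], events,
                                    delta, cfg)
    cbind(data.frame(guid = record$guid, epoch_index = e$epoch_index,
                     start_s = e$start_s, end_s = e$end_s,
                     interpretable_fraction = e$interpretable_fraction),
          seqf, varf)
  })
  out <- data.table::rbindlist(rows, fill = TRUE)
  as.data.frame(out)
}
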