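# Dense-representation oracles for the segmented-signal algebra, and
# O(n^2)/O(n^3) brute-force oracles for the feature battery.  These stay
# deliberately naive and independent of the package internals.

DELTA <- 0.25

# Random gappy signal on the 0.25 s grid (integer grid offsets).
random_sig <- function(max_segs = 5, max_len = 30, max_gap = 20,
                       origin_range = c(-400L, 0L)) {
  nseg <- sample.int(max_segs, 1)
  lens <- sample.int(max_len, nseg, replace = TRUE)
  gaps <- if (nseg > 1) sample.int(max_gap, nseg - 1, replace = TRUE)
    else integer(0)
  origin <- sample(origin_range[1]:origin_range[2], 1)
  starts <- origin + cumsum(c(0L, head(lens, -1) + gaps))
  seg_signal(stats::rnorm(sum(lens), 140, 8), starts * DELTA, lens,
             DELTA)
}

# Dense oracle: NA-marked vector on the full grid with integer indices.
dense_of <- function(s) {
  if (ctgkit::n_samples(s) == 0L)
    return(list(grid = integer(0), values = numeric(0)))
  g <- round(ctgkit::sample_times(s) / s$delta)
  grid <- min(g):max(g)
  v <- rep(NA_real_, length(grid))
  v[g - min(g) + 1L] <- s$data
  list(grid = grid, values = v)
}

oracle_find_gaps <- function(s) {
  d <- dense_of(s)
  isna <- is.na(d$values)
  r <- rle(isna)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  sel <- which(r$values)
  data.frame(gap_start = d$grid[starts[sel]] * DELTA,
             gap_end = (d$grid[ends[sel]] + 1L) * DELTA,
             duration = r$lengths[sel] * DELTA)
}

oracle_intersect_mask <- function(a, b) {
  # common-support sample grids via the AND of missing-markers
  da <- dense_of(a); db <- dense_of(b)
  ga <- da$grid[!is.na(da$values)]
  gb <- db$grid[!is.na(db$values)]
  # supports are half-open unions of segment extents; a grid point of a
  # is in b's support if it falls inside one of b's segments
  in_support <- function(g, s) {
    iv <- cbind(round(s$seg_start / s$delta),
                round(s$seg_start / s$delta) + s$seg_len)
    out <- rep(FALSE, length(g))
    for (k in seq_len(nrow(iv)))
      out <- out | (g >= iv[k, 1] & g < iv[k, 2])
    out
  }
  list(a_keep = in_support(ga, b), b_keep = in_support(gb, a),
       a_grid = ga, b_grid = gb)
}

# Brute-force ApEn with self-matches (Chebyshev distance).
brute_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    cnt <- numeric(n - mm + 1)
    for (i in 1:(n - mm + 1)) {
      c_i <- 0
      for (j in 1:(n - mm + 1)) {
        d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
        if (d <= r) c_i <- c_i + 1
      }
      cnt[i] <- c_i / (n - mm + 1)
    }
    mean(log(cnt))
  }
  phi(m) - phi(m + 1)
}

# Brute-force SampEn without self-matches.
brute_sampen <- function(x, m, r) {
  n <- length(x)
  count <- function(mm) {
    tot <- 0
    for (i in 1:(n - m)) for (j in 1:(n - m)) {
      if (i == j) next
      d <- max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)]))
      if (d <= r) tot <- tot + 1
    }
    tot
  }
  -log(count(m + 1) / count(m))
}

# Brute-force PRSA by direct loops.
brute_prsa <- function(x, delta, anchors, T_s, L_s) {
  Tn <- round(T_s / delta); Ln <- max(2L * Tn, round(L_s / delta))
  n <- length(x)
  idx <- c()
  for (i in (Ln + 1):(n - Ln)) {
    after <- mean(x[i:(i + Tn - 1)])
    before <- mean(x[(i - Tn):(i - 1)])
    if ((anchors == "increment" && after > before) ||
        (anchors == "decrement" && after < before)) idx <- c(idx, i)
  }
  if (length(idx) == 0) return(NA_real_)
  prof <- sapply((-Ln):(Ln - 1), function(o) mean(x[idx + o]))
  names(prof) <- (-Ln):(Ln - 1)
  blk <- function(o0) mean(prof[as.character(o0:(o0 + Tn - 1))])
  (blk(0) + blk(Tn) - blk(-Tn) - blk(-2 * Tn)) / 4
}

# Write a tall tracing CSV from row vectors (header per the transformed
# record structure).
write_tall_csv <- function(path, guid, trace_ms, meas, sensor, monitor,
                           reading, recorded_ms = trace_ms) {
  df <- data.frame(`Tracing GUID` = guid, `Trace DT` = trace_ms,
                   `Recorded DT` = recorded_ms, Measurement = meas,
                   Sensor = sensor, Monitor = monitor, Reading = reading,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
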