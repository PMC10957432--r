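flat_record <- function(x, delta = 0.25, guid = "G",
                        ua = NULL) {
  n <- length(x)
  tt <- -n * delta + (seq_len(n) - 1L) * delta
  sigs <- list(FHR = build_segmented(tt, x, delta, "FHR"))
  if (!is.null(ua)) sigs$UA <- build_segmented(tt, ua, delta, "UA",
                                               "0-100")
  efm_record(guid, sigs, stage = "repaired")
}

test_that("a flat hour yields a single baseline event with level and slope", {
  x <- rep(140, 14400)
  rec <- flat_record(x)
  ev <- detect_patterns(rec)
  bas <- ev[ev$type == "BAS", ]
  expect_equal(nrow(bas), 1L)
  expect_equal(bas$level, 140)
  expect_equal(bas$slope, 0)
  expect_equal(bas$end_s - bas$start_s, 3600)
})

test_that("a planted deceleration does not drag the baseline", {
  delta <- 0.25
  n <- 14400
  tt_rel <- (seq_len(n) - 1L) * delta
  x <- rep(140, n)
  dip <- tt_rel >= 1800 & tt_rel < 1860   # 60 s deceleration
  u <- (tt_rel[dip] - 1800) / 60
  x[dip] <- 140 - 30 * ifelse(u < 0.5, u * 2, (1 - u) * 2)
  b <- estimate_baseline(x, delta)
  expect_true(all(abs(b - 140) < 1))
})

test_that("linear drift is recovered as the baseline slope", {
  n <- 14400
  x <- seq(140, 150, length.out = n)
  rec <- flat_record(x)
  ev <- detect_patterns(rec)
  bas <- ev[ev$type == "BAS", ]
  expect_equal(nrow(bas), 1L)
  # slope reported per minute; 10 bpm over one hour
  expect_equal(bas$slope * 60, 10, tolerance = 0.05)
})

test_that("acceleration/deceleration thresholds are strict", {
  delta <- 0.25
  mk <- function(amount, dur_s) {
    n <- 9600
    x <- rep(140, n)
    tt_rel <- (seq_len(n) - 1L) * delta
    sel <- tt_rel >= 1000 & tt_rel < 1000 + dur_s
    x[sel] <- 140 + amount
    detect_patterns(flat_record(x))
  }
  # +20 bpm for 20 s: one acceleration of height 20
  ev <- mk(20, 20)
  acc <- ev[ev$type == "ACC", ]
  expect_equal(nrow(acc), 1L)
  expect_equal(acc$height, 20)
  expect_equal(acc$area, 20 * 20 / 60, tolerance = 0.01)

  # exactly +15.0 bpm: never an event, regardless of duration
  expect_equal(sum(mk(15, 60)$type == "ACC"), 0L)

  # -20 bpm for exactly 15.0 s: no deceleration
  expect_equal(sum(mk(-20, 15)$type == "DEC"), 0L)
  # -20 bpm for 15.25 s: a deceleration
  expect_equal(sum(mk(-20, 15.25)$type == "DEC"), 1L)
})

test_that("deceleration subtypes follow duration, abruptness and pairing", {
  cons <- data.frame(start_s = -300, end_s = -230, peak_s = -265,
                     type = "CON")
  mk_dec <- function(dur, o2n, nadir_s = NULL) {
    data.frame(start_s = -280, end_s = -280 + dur,
               nadir_s = if (is.null(nadir_s)) -280 + o2n else nadir_s,
               onset_to_nadir_s = o2n)
  }
  expect_equal(classify_deceleration(mk_dec(130, 60), cons), "prolonged")
  expect_equal(classify_deceleration(mk_dec(60, 10), cons), "variable")
  # gradual, nadir 25 s after the contraction peak: late
  expect_equal(classify_deceleration(mk_dec(60, 40, nadir_s = -240),
                                     cons), "late")
  # gradual, nadir at the peak: early
  expect_equal(classify_deceleration(mk_dec(60, 40, nadir_s = -265),
                                     cons), "early")
  # gradual but unpaired: variable
  expect_equal(classify_deceleration(mk_dec(60, 40), NULL), "variable")
})

test_that("planted contractions are recovered with height and count", {
  delta <- 0.25
  n <- 4800 * 3
  tt <- -n * delta + (seq_len(n) - 1L) * delta
  ua <- rep(10, n)
  starts <- seq(min(tt) + 200, -300, by = 180)[1:6]
  for (s0 in starts) {
    sel <- tt >= s0 & tt < s0 + 70
    u <- (tt[sel] - s0) / 70
    ua[sel] <- 10 + 40 * 0.5 * (1 - cos(2 * pi * u))
  }
  sig <- build_segmented(tt, ua, delta, "UA", "0-100")
  cons <- detect_contractions(sig)
  expect_equal(nrow(cons), 6L)
  expect_true(all(abs(cons$height - 40) < 2))
  # flat UA: nothing
  flat <- build_segmented(tt, rep(10, n), delta, "UA", "0-100")
  expect_equal(nrow(detect_contractions(flat)), 0L)
})

test_that("BAS/ACC/DEC/RIN partition the interpretable timeline", {
  set.seed(21)
  cfg <- sim_config(seed = 21, duration_h = 2, variability_bpm = 2,
                    dropout_rate = 0.01, duplicate_rate = 0,
                    sensor_switch_frac = NA)
  p <- tempfile(fileext = ".csv")
  simulate_tracing(cfg, p)
  res <- process_tracing(p)
  fhr <- res$repaired$signals$FHR
  tt <- sample_times(fhr)
  ev <- res$events
  fhr_ev <- ev[ev$type %in% c("BAS", "ACC", "DEC", "RIN"), ]
  # no overlap among FHR events
  fhr_ev <- fhr_ev[order(fhr_ev$start_s), ]
  if (nrow(fhr_ev) > 1)
    expect_true(all(fhr_ev$start_s[-1] >=
                      fhr_ev$end_s[-nrow(fhr_ev)] - 1e-9))
  # every interpretable sample is covered by exactly one FHR event
  noi <- res$noi
  keep <- rep(TRUE, length(tt))
  if (nrow(noi)) for (k in seq_len(nrow(noi)))
    keep <- keep & !(tt >= noi$start_s[k] & tt < noi$end_s[k])
  covered <- rep(0L, sum(keep))
  kt <- tt[keep]
  for (k in seq_len(nrow(fhr_ev)))
    covered <- covered + (kt >= fhr_ev$start_s[k] - 1e-9 &
                            kt < fhr_ev$end_s[k] - 1e-9)
  expect_true(all(covered == 1L))
})

test_that("short interpretable spans yield RIN, not a baseline", {
  delta <- 0.25
  tt <- -100 + (0:359) * delta          # 90 s span
  rec <- efm_record("G", list(FHR = build_segmented(tt, rep(140, 360),
                                                    delta, "FHR")),
                    stage = "repaired")
  ev <- detect_patterns(rec)
  expect_equal(ev$type, "RIN")
})
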