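test_that("epoch retention boundary sits exactly at 3840 samples", {
  delta <- 0.25
  mk_epoch_record <- function(n_keep) {
    # one epoch [-1200, 0); keep the first n_keep samples
    tt <- -1200 + (seq_len(n_keep) - 1L) * delta
    efm_record("G", list(FHR = build_segmented(tt, rep(140, n_keep),
                                               delta, "FHR")),
               stage = "repaired")
  }
  e_full <- segment_epochs(mk_epoch_record(4800))
  expect_true(e_full$retained)
  expect_equal(e_full$interpretable_fraction, 1.0)
  expect_false(segment_epochs(mk_epoch_record(3839))$retained)
  expect_true(segment_epochs(mk_epoch_record(3840))$retained)
})

test_that("sequential features count dwell, transitions and rates", {
  ev_bas <- data.frame(guid = "G", type = "BAS", start_s = -1200,
                       end_s = 0, subtype = NA, nadir_s = NA,
                       peak_s = NA)
  s <- sequential_features(ev_bas, -1200, 0)
  expect_equal(s$dwell_BAS, 1200)
  expect_true(all(unlist(s[grepl("^trans_", names(s))]) == 0))

  ev <- data.frame(
    guid = "G", type = c("BAS", "DEC", "BAS"),
    start_s = c(-1200, -600, -540), end_s = c(-600, -540, 0),
    subtype = c(NA, "variable", NA), nadir_s = c(NA, -570, NA),
    peak_s = NA)
  s2 <- sequential_features(ev, -1200, 0)
  expect_equal(s2$trans_BAS_DEC, 1L)
  expect_equal(s2$trans_DEC_BAS, 1L)
  expect_equal(s2$dwell_DEC, 60)
  expect_equal(s2$dec_abrupt, 1L)

  cons <- data.frame(guid = "G", type = rep("CON", 6),
                     start_s = seq(-1150, -150, length.out = 6),
                     end_s = seq(-1150, -150, length.out = 6) + 70,
                     subtype = NA, nadir_s = NA,
                     peak_s = seq(-1150, -150, length.out = 6) + 35)
  s3 <- sequential_features(cons, -1200, 0)
  expect_equal(s3$con_rate_per10min, 3.0)
})

test_that("cumulative dwell sums event time before the epoch", {
  ev <- data.frame(guid = "G", type = c("BAS", "BAS"),
                   start_s = c(-3600, -1200), end_s = c(-1500, 0),
                   subtype = NA, nadir_s = NA, peak_s = NA)
  s <- sequential_features(ev, -1200, 0)
  expect_equal(s$cumdwell_BAS, 2100)
})

test_that("spectral decomposition reconstructs and separates bands", {
  set.seed(31)
  x <- rnorm(4800, 140, 5)
  comp <- decompose_spectral(x, 0.25, 0.030)
  expect_lt(max(abs(comp$low + comp$high - x)), 1e-9 * max(abs(x)))

  tt <- (0:4799) * 0.25
  slow <- sin(2 * pi * 0.010 * tt)
  comp_s <- decompose_spectral(slow, 0.25, 0.030)
  expect_gt(var(comp_s$low), 0.99 * var(slow))
  expect_lt(var(comp_s$high), 0.02 * var(slow))

  fast <- sin(2 * pi * 0.2 * tt)
  comp_f <- decompose_spectral(fast, 0.25, 0.030)
  expect_gt(var(comp_f$high), 0.99 * var(fast))
})

test_that("PRSA matches the brute-force oracle and its symmetries", {
  # constant signal: no anchors
  expect_true(is.na(prsa(rep(5, 500), 0.25, "increment")$value))

  set.seed(33)
  for (i in 1:5) {
    x <- as.numeric(arima.sim(list(ar = 0.8), 400)) + 140
    for (anch in c("increment", "decrement")) {
      got <- prsa(x, 0.25, anch)$value
      want <- brute_prsa(x, 0.25, anch, 2.5, 25)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }

  # square wave alternating at the T scale
  sq <- rep(rep(c(1, -1), each = 10), 30)
  ac <- prsa(sq, 0.25, "increment")$value
  dc <- prsa(sq, 0.25, "decrement")$value
  expect_equal(ac, brute_prsa(sq, 0.25, "increment", 2.5, 25))
  expect_equal(abs(ac), abs(dc), tolerance = 1e-12)

  # white noise: AC ~ -DC by symmetry
  set.seed(34)
  w <- rnorm(100000)
  pf <- prsa_features(w, 0.25)
  expect_equal(pf[["AC"]], -pf[["DC"]], tolerance = 0.02)
  expect_equal(pf[["DR"]], pf[["DC"]] - pf[["AC"]])
})

test_that("Lomb-Scargle band powers localize planted sinusoids despite gaps", {
  set.seed(35)
  tt <- (0:2399) * 0.25
  # delete 20 % of samples as one contiguous transmission gap
  keep <- setdiff(seq_len(2400), 1000:1479)
  for (case in list(c(0.1, 1), c(0.3, 2), c(0.7, 3))) {
    f0 <- case[1]
    x <- sin(2 * pi * f0 * tt) + 0.01 * rnorm(2400)
    b <- lomb_bands(tt[keep], x[keep])
    dom <- names(which.max(b[c("LF", "MF", "HF")]))
    want <- c("LF", "MF", "HF")[case[2]]
    expect_equal(dom, want)
    expect_gt(b[[dom]] / sum(b[c("LF", "MF", "HF")]), 0.95)
  }
})

test_that("entropies match brute-force oracles and order regularity", {
  # constant: degenerate zero
  e0 <- entropies(rep(7, 200))
  expect_true(all(e0$ApEn == 0) && all(e0$SampEn == 0))
  expect_true(all(e0$degenerate))

  set.seed(36)
  x30 <- rnorm(30)
  for (r in c(0.2, 0.3)) {
    e <- entropies(x30, 2L, r)
    expect_equal(e$ApEn, brute_apen(x30, 2, r * sd(x30)),
                 tolerance = 1e-12)
    want_se <- brute_sampen(x30, 2, r * sd(x30))
    if (is.finite(want_se)) {
      expect_equal(e$SampEn, want_se, tolerance = 1e-12)
    } else {
      # no length-3 matches at this tolerance: flagged invalid
      expect_true(is.na(e$SampEn))
    }
  }
  x80 <- as.numeric(arima.sim(list(ar = 0.9), 80))
  e80 <- entropies(x80, 2L, 0.2)
  expect_equal(e80$ApEn, brute_apen(x80, 2, 0.2 * sd(x80)),
               tolerance = 1e-12)
  expect_equal(e80$SampEn, brute_sampen(x80, 2, 0.2 * sd(x80)),
               tolerance = 1e-12)

  # periodic sawtooth is more regular than its shuffle
  saw <- rep(seq(0, 1, length.out = 20), 15)
  set.seed(37)
  shuf <- sample(saw)
  expect_lt(entropies(saw, 2L, 0.2)$SampEn,
            entropies(shuf, 2L, 0.2)$SampEn)
})

test_that("Hurst exponent of white noise is 1/2 and persistence raises it", {
  set.seed(38)
  h_wn <- mean(replicate(10, hurst_rs(rnorm(4096))))
  expect_equal(h_wn, 0.5, tolerance = 0.2)
  set.seed(39)
  e <- rnorm(4096)
  wn <- hurst_rs(e)
  ar1 <- hurst_rs(as.numeric(stats::filter(e, 0.9,
                                           method = "recursive")))
  expect_gt(ar1, wn)
})

test_that("nonlinear measures are deterministic and sane", {
  set.seed(40)
  x <- as.numeric(arima.sim(list(ar = 0.7), 1500))
  expect_identical(lyapunov_exponent(x), lyapunov_exponent(x))
  expect_identical(correlation_dimension(x), correlation_dimension(x))
  expect_true(is.na(hurst_rs(rep(3, 1000))))
  expect_true(is.na(correlation_dimension(rep(3, 1000))))
  # a 2-d random embedding should have correlation dimension near 2,
  # certainly above a sine's ~1
  d2_noise <- correlation_dimension(rnorm(1500))
  d2_sine <- correlation_dimension(sin(2 * pi * (1:1500) / 50))
  expect_gt(d2_noise, d2_sine)
})

test_that("classical variability indices obey their closed forms", {
  # constant
  cv0 <- classical_variability(rep(140, 4800))
  expect_equal(cv0[["STV"]], 0)
  expect_equal(cv0[["Delta"]], 0)

  # alternation 130/140 on the 2.5 s grid: STV = 10
  g <- rep(c(130, 140), 120)
  x <- rep(g, each = 10)          # 4 Hz samples, constant within steps
  cv <- classical_variability(x)
  expect_equal(cv[["STV"]], 10)

  # 1-min sawtooth between 120 and 150: Delta = 30
  saw <- rep(c(seq(120, 150, length.out = 120),
               seq(150, 120, length.out = 120)), 10)
  cv2 <- classical_variability(saw)
  expect_equal(cv2[["Delta"]], 30)

  # II verified against its direct formula on white noise
  set.seed(41)
  w <- rnorm(4800, 140, 10)
  cvw <- classical_variability(w)
  gw <- w[seq(1, 4800, by = 10)]
  expect_equal(cvw[["II"]], mean(abs(diff(gw))) / sd(gw))
  expect_equal(cvw[["LTI"]],
               unname(diff(quantile(sqrt(gw[-length(gw)]^2 + gw[-1]^2),
                                    c(0.25, 0.75)))))
})

test_that("the default feature mask yields the printed cell pattern", {
  m <- default_ctg_feature_mask()
  key <- paste(m$feature, m$event, m$band)
  # mean/SD in all six cells
  for (ev in c("BAS", "ACC", "DEC")) for (b in c("low", "high")) {
    expect_true(paste("mean", ev, b) %in% key)
    expect_true(paste("sd", ev, b) %in% key)
  }
  # slope only BAS-low
  expect_equal(sum(m$feature == "slope"), 1L)
  expect_true("slope BAS low" %in% key)
  # height/area only on ACC/DEC slow components
  expect_setequal(key[m$feature == "height"],
                  c("height ACC low", "height DEC low"))
  # the variability battery sits on the high components of all 3 events
  expect_setequal(unique(m$band[m$feature == "STV"]), "high")
  expect_equal(sum(m$feature == "SampEn_0.2"), 3L)
})

test_that("feature matrix populates masked cells and flags absent events", {
  delta <- 0.25
  tt <- -1200 + (0:4799) * delta
  set.seed(42)
  x <- 140 + rnorm(4800, 0, 3)
  ev <- data.frame(guid = "G", type = "BAS", start_s = -1200, end_s = 0,
                   subtype = NA, nadir_s = NA, peak_s = NA)
  fm <- assemble_feature_matrix(tt, x, ev, delta)
  expect_equal(fm[["mean__BAS__low"]] + 0, mean(decompose_spectral(
    x, delta)$low), tolerance = 1e-9)
  expect_false(is.na(fm[["SampEn_0.2__BAS__high"]]))
  # no ACC events: those cells are invalid
  expect_true(is.na(fm[["mean__ACC__low"]]))
  expect_true(is.na(fm[["STV__DEC__high"]]))
})

test_that("overriding the mask adds cells without changing existing ones", {
  delta <- 0.25
  tt <- -1200 + (0:4799) * delta
  set.seed(43)
  x <- 140 + rnorm(4800, 0, 3)
  ev <- data.frame(guid = "G", type = "BAS", start_s = -1200, end_s = 0,
                   subtype = NA, nadir_s = NA, peak_s = NA)
  base_mask <- default_ctg_feature_mask()
  fm1 <- assemble_feature_matrix(tt, x, ev, delta, mask = base_mask)
  wider <- rbind(base_mask,
                 data.frame(feature = "STV", event = "BAS", band = "low"))
  fm2 <- assemble_feature_matrix(tt, x, ev, delta, mask = wider)
  expect_true("STV__BAS__low" %in% names(fm2))
  for (nm in names(fm1)) expect_equal(fm2[[nm]], fm1[[nm]])
})
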