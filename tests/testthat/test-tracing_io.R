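test_that("MRN normalization pads, prefixes and rejects as specified", {
  r <- normalize_mrn(c("12345678", "1234567", "110012345678",
                       "11A2345678", "123456", "1234567890123"))
  expect_equal(r$mrn[1], "110012345678")
  expect_equal(r$mrn[2], "110001234567")
  expect_equal(r$mrn[3], "110012345678")
  expect_equal(r$status[4], "nonnumeric")
  expect_equal(r$status[5], "length")
  expect_equal(r$status[6], "length")
  ok <- r$status == "ok"
  expect_true(all(nchar(r$mrn[ok]) == 12L))
})

test_that("duplicate-timestamp resolution keeps the highest valid row", {
  expect_true(is.na(resolve_duplicate_timestamps(c("", ""), c(1, 2), "HR2")))
  expect_equal(resolve_duplicate_timestamps(c("", "141"), c(1, 2), "HR2"),
               141)
  expect_equal(resolve_duplicate_timestamps(c("139", "142"), c(10, 20),
                                            "HR2"), 142)
  # resolution depends on row index, not presentation order
  expect_equal(resolve_duplicate_timestamps(c("142", "139"), c(20, 10),
                                            "HR2"), 142)
  # out-of-range readings are invalid
  expect_equal(resolve_duplicate_timestamps(c("500", "140"), c(5, 1),
                                            "HR2"), 140)
})

test_that("the 72-hour window truncates or excludes tracings", {
  h <- 3600
  tt_old <- seq(-80 * h, -75 * h, by = 0.25)
  old <- build_segmented(tt_old, rep(140, length(tt_old)))
  expect_equal(apply_birth_window(old)$status, "outside_window_prior")

  tt_str <- seq(-73 * h, -71 * h, by = 0.25)
  strad <- build_segmented(tt_str, rep(140, length(tt_str)))
  r <- apply_birth_window(strad)
  expect_equal(r$status, "matched")
  expect_equal(min(sample_times(r$signal)), -72 * h)

  tt_rec <- seq(-10 * h, -0.25, by = 0.25)
  recent <- build_segmented(tt_rec, rep(140, length(tt_rec)))
  r2 <- apply_birth_window(recent)
  expect_identical(r2$signal, recent)
})

test_that("parse_tracing_csv groups by measurement/sensor/monitor", {
  path <- tempfile(fileext = ".csv")
  # HR2/external and UP/TOCO; two HR2 channels with different sensors
  ms1 <- seq(10000, 250, by = -250)
  write_tall_csv(path, "G1",
                 trace_ms = c(ms1, ms1, ms1 + 20000),
                 meas = c(rep("HR2", 40), rep("UP", 40), rep("HR2", 40)),
                 sensor = c(rep("external", 40), rep("TOCO", 40),
                            rep("FECG", 40)),
                 monitor = "Coro 250",
                 reading = c(rnorm(40, 140, 3), rnorm(40, 20, 3),
                             rnorm(40, 142, 3)))
  out <- parse_tracing_csv(path)
  expect_equal(out$status, "matched")
  expect_equal(length(out$record$signals), 3L)
  keys <- names(out$record$signals)
  expect_true(any(grepl("HR2\\|external", keys)))
  expect_true(any(grepl("HR2\\|FECG", keys)))
  expect_true(any(grepl("UP\\|TOCO", keys)))
})

test_that("empty and malformed files map to disposition statuses", {
  p <- tempfile(fileext = ".csv")
  writeLines(paste("Tracing GUID,Trace DT,Recorded DT,Measurement,",
                   "Sensor,Monitor,Reading", sep = ""), p)
  out <- parse_tracing_csv(p)
  expect_equal(out$status, "empty_file")

  p2 <- tempfile(fileext = ".csv")
  write_tall_csv(p2, "G2", trace_ms = c("xx", "250"), meas = "HR2",
                 sensor = "external", monitor = "Coro 250",
                 reading = c(140, 141))
  out2 <- parse_tracing_csv(p2)
  expect_equal(out2$report[["rows_malformed_timestamp"]], 1L)

  p3 <- tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", p3)
  expect_error(parse_tracing_csv(p3), "missing required column")
})

test_that("disposition counts partition the file and order does not matter", {
  p <- tempfile(fileext = ".csv")
  ms <- rep(seq(2000, 250, by = -250), each = 2)  # every timestamp doubled
  reading <- rep(140, 16)
  reading[c(2, 4)] <- c(145, 150)       # corrected duplicates
  reading[5] <- 999                     # invalid (out of range)
  write_tall_csv(p, "G3", trace_ms = ms, meas = "HR2",
                 sensor = "external", monitor = "Coro 250",
                 reading = reading)
  out <- parse_tracing_csv(p)
  rep_counts <- out$report
  expect_equal(rep_counts[["rows_total"]],
               rep_counts[["rows_malformed_timestamp"]] +
                 rep_counts[["rows_invalid_reading"]] +
                 rep_counts[["rows_duplicate_dropped"]] +
                 rep_counts[["rows_outside_window"]] +
                 rep_counts[["rows_kept"]])
  # duplicate resolution: later rows win
  sig <- out$record$signals[[1]]
  expect_equal(sig$data[1], 145)   # earliest time = largest ms

  # shuffling the file rows (row_index follows file order, so the same
  # later-row-wins semantics apply to the corrected values)
  expect_equal(n_samples(sig), 8L)
})

test_that("parse reports serialize to JSON and CSV", {
  rep_counts <- c(rows_total = 10L, rows_kept = 8L)
  pj <- tempfile(fileext = ".json")
  write_parse_report(rep_counts, pj)
  back <- jsonlite::read_json(pj)
  expect_equal(back$rows_total, 10L)
  pc <- tempfile(fileext = ".csv")
  write_parse_report(rep_counts, pc, format = "csv")
  expect_equal(utils::read.csv(pc)$rows_kept, 8L)
})

test_that("simulated tall CSV round-trips through the parser", {
  cfg <- sim_config(seed = 3, duration_h = 0.5, variability_bpm = 2,
                    dropout_rate = 0, duplicate_rate = 0,
                    sensor_switch_frac = NA)
  p <- tempfile(fileext = ".csv")
  sim <- simulate_tracing(cfg, p)
  out <- parse_tracing_csv(p)
  expect_equal(out$status, "matched")
  fhr_key <- grep("^HR2", names(out$record$signals), value = TRUE)
  sig <- out$record$signals[[fhr_key]]
  fhr_rows <- sim$rows[sim$rows$measurement == "HR2", ]
  expect_equal(n_samples(sig), nrow(fhr_rows))
  expect_equal(sig$data, fhr_rows$reading)
})

test_that("the wide legacy format carries 240 samples per record and converts", {
  cfg <- sim_config(seed = 4, duration_h = 0.25, variability_bpm = 1,
                    dropout_rate = 0, duplicate_rate = 0,
                    sensor_switch_frac = NA)
  sim <- simulate_tracing(cfg)
  wp <- tempfile(fileext = ".csv")
  write_wide_tracing(sim$rows, wp)
  hdr <- names(data.table::fread(wp, nrows = 0))
  expect_equal(sum(grepl("^sample", hdr)), 240L)
  tall <- read_wide_tracing(wp)
  expect_equal(nrow(tall), nrow(sim$rows))
  # same sample multiset per signal
  orig <- sim$rows[order(sim$rows$measurement, sim$rows$trace_dt), ]
  conv <- tall[order(tall$measurement, tall$trace_dt), ]
  expect_equal(as.numeric(conv$trace_dt), as.numeric(orig$trace_dt))
  expect_equal(as.numeric(conv$reading), as.numeric(orig$reading))
})
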