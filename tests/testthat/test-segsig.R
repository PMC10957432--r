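test_that("build_segmented groups contiguous runs into segments", {
  t1 <- seq(0, 6.25, by = 0.25)
  t2 <- seq(10, 14.75, by = 0.25)
  s <- build_segmented(c(t1, t2), rnorm(length(t1) + length(t2)))
  expect_equal(n_segments(s), 2L)
  expect_equal(s$seg_len, c(26L, 20L))
  expect_equal(onset_pointers(s), c(1L, 27L))
  expect_equal(onset_offsets(s), c(0L, 26L))

  s1 <- build_segmented((0:4799) * 0.25, rnorm(4800))
  expect_equal(n_segments(s1), 1L)

  expect_error(build_segmented(c(0, 0.25, 0.2), 1:3), "unsorted")
  expect_error(build_segmented(c(0, 0.25, 0.63), 1:3), "off-grid")
})

test_that("the printed five-segment FHR example reconstructs exactly", {
  lens <- c(26136L, 11704L, 30764L, 26880L, 66212L)
  # starts only need valid spacing; use printed hours converted to s
  starts_h <- c(-16.5108, -14.6275, -13.0372, -9.5442, -7.6442)
  s <- seg_signal(rep(0, sum(lens)), starts_h * 3600, lens)
  expect_equal(n_samples(s), 161696L)
  expect_equal(onset_pointers(s), c(1L, 26137L, 37841L, 68605L, 95485L))
})

test_that("find_gaps reports inter-segment intervals", {
  t1 <- seq(0, 6.25, by = 0.25)
  t2 <- seq(10, 14.75, by = 0.25)
  s <- build_segmented(c(t1, t2), rnorm(46))
  g <- find_gaps(s)
  expect_equal(nrow(g), 1L)
  expect_equal(g$gap_start, 6.50)
  expect_equal(g$gap_end, 10.00)
  expect_equal(g$duration, 3.50)

  s1 <- build_segmented(t1, rnorm(26))
  expect_equal(nrow(find_gaps(s1)), 0L)
})

test_that("gap durations of the printed five-segment signal match direct arithmetic", {
  lens <- c(26136L, 11704L, 30764L, 26880L, 66212L)
  starts <- c(-16.5108, -14.6275, -13.0372, -9.5442, -7.6442) * 3600
  s <- seg_signal(rep(0, sum(lens)), starts, lens)
  g <- find_gaps(s)
  expect_equal(nrow(g), 4L)
  # independent arithmetic: next start minus (start + len * 0.25);
  # printed hours carry 4 decimals, so allow their rounding (±0.36 s)
  expected <- starts[-1] - (starts[-5] + lens[-5] * 0.25)
  expect_equal(g$duration, expected)
  expect_equal(g$duration[1], 245.88, tolerance = 0.4 / 245)
})

test_that("to_dense/from_dense round trip is the identity", {
  t1 <- seq(0, 6.25, by = 0.25)
  t2 <- seq(10, 14.75, by = 0.25)
  s <- build_segmented(c(t1, t2), rnorm(46))
  d <- to_dense(s)
  expect_equal(length(d$values), 60L)
  expect_equal(sum(is.na(d$values)), 14L)
  s2 <- from_dense(d)
  expect_equal(s2$data, s$data)
  expect_equal(sample_times(s2), sample_times(s))

  # gapless: dense equals data
  s1 <- build_segmented(t1, rnorm(26))
  expect_equal(to_dense(s1)$values, s1$data)

  expect_error(from_dense(list(time = c(0, 0.3, 0.6), values = 1:3)),
               "off-grid")
})

test_that("round trip holds on fuzzed signals", {
  set.seed(42)
  for (i in 1:200) {
    s <- random_sig()
    s2 <- from_dense(to_dense(s))
    expect_equal(s2$seg_len, s$seg_len)
    expect_equal(s2$seg_start, s$seg_start)
    expect_equal(s2$data, s$data)
  }
})

test_that("intersect restricts to common support", {
  a <- build_segmented((0:399) * 0.25, rnorm(400))        # [0, 100)
  b <- build_segmented((200:599) * 0.25, rnorm(400))      # [50, 150)
  r <- sig_intersect(a, b)
  expect_equal(range(sample_times(r$a)), c(50, 99.75))
  expect_equal(range(sample_times(r$b)), c(50, 99.75))
  # values unchanged
  expect_equal(r$a$data, a$data[201:400])

  disj <- sig_intersect(build_segmented((0:9) * 0.25, rnorm(10)),
                        build_segmented((100:109) * 0.25, rnorm(10)))
  expect_equal(n_samples(disj$a), 0L)
  expect_equal(n_samples(disj$b), 0L)

  bad <- build_segmented((0:9) * 0.5, rnorm(10), delta = 0.5)
  expect_error(sig_intersect(a, bad), "delta mismatch")
})

test_that("concatenate merges disjoint parts and fuses abutting ones", {
  a <- build_segmented((0:9) * 0.25, rnorm(10))
  b <- build_segmented((10:19) * 0.25, rnorm(10))   # abuts a
  ab <- sig_concat(list(a, b))
  expect_equal(n_segments(ab), 1L)
  expect_equal(n_samples(ab), 20L)

  c2 <- build_segmented((40:49) * 0.25, rnorm(10))
  abc <- sig_concat(list(c2, a, b))   # shuffled order
  expect_equal(n_segments(abc), 2L)
  expect_equal(abc$data, c(a$data, b$data, c2$data))

  ov <- build_segmented((5:14) * 0.25, rnorm(10))
  expect_error(sig_concat(list(a, ov)), "overlap")
})

test_that("algebra operations match the dense-representation oracle on fuzzed signals", {
  set.seed(7)
  for (i in 1:300) {
    s <- random_sig()
    g <- find_gaps(s)
    og <- oracle_find_gaps(s)
    expect_equal(g$gap_start, og$gap_start)
    expect_equal(g$duration, og$duration)

    a <- random_sig(); b <- random_sig()
    r <- sig_intersect(a, b)
    om <- oracle_intersect_mask(a, b)
    expect_equal(round(sample_times(r$a) / 0.25), om$a_grid[om$a_keep])
    expect_equal(round(sample_times(r$b) / 0.25), om$b_grid[om$b_keep])
    expect_equal(r$a$data, a$data[om$a_keep])
    # conservation: intersect never increases sample count
    expect_lte(n_samples(r$a), n_samples(a))
  }
})

test_that("concatenate conserves sample count on fuzzed disjoint parts", {
  set.seed(11)
  for (i in 1:100) {
    a <- random_sig(origin_range = c(-700L, -600L))
    b <- random_sig(origin_range = c(-300L, -100L))
    ab <- sig_concat(list(b, a))
    expect_equal(n_samples(ab), n_samples(a) + n_samples(b))
    expect_equal(find_gaps(ab)$duration,
                 oracle_find_gaps(ab)$duration)
  }
})

test_that("efm_record enforces the one-signal-per-measurement rule", {
  s1 <- build_segmented((0:9) * 0.25, rnorm(10), measurement = "FHR")
  s2 <- build_segmented((20:29) * 0.25, rnorm(10), measurement = "FHR")
  expect_error(efm_record("g", list(a = s1, b = s2), stage = "combined"),
               "at most one")
  r <- efm_record("g", list(a = s1, b = s2), stage = "raw")
  expect_s3_class(r, "efm_record")
})
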