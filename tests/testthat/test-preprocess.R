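test_that("zero_mean subtracts the mean exactly", {
  expect_equal(zero_mean(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(zero_mean(rep(7.5, 20)), rep(0, 20))
  set.seed(1)
  x <- rnorm(5000, mean = 3)
  expect_lte(abs(mean(zero_mean(x))), 1e-12 * max(abs(x)))
  expect_error(zero_mean(numeric(0)), "nonempty")
})

test_that("band-pass preserves the passband and rejects drift", {
  fs <- 100
  t <- (0:5999) / fs
  idx <- interior(6000)
  tone <- sin(2 * pi * 1 * t)
  y <- bandpass_fir(tone, filter_spec(0.5, 40, 400), fs)
  expect_lt(abs(sqrt(mean(y[idx]^2)) / sqrt(mean(tone[idx]^2)) - 1), 0.05)

  drift <- sin(2 * pi * 0.05 * t)
  yd <- bandpass_fir(drift, filter_spec(0.5, 40, 400), fs)
  expect_lt(sqrt(mean(yd[idx]^2)) / sqrt(mean(drift[idx]^2)), 0.10)

  expect_equal(bandpass_fir(rep(0, 2000), fs = fs), rep(0, 2000),
               ignore_attr = TRUE)
  md <- attr(bandpass_fir(tone, fs = fs), "fir_metadata")
  expect_identical(md$n_taps, 401L)
  expect_gt(md$stopband_atten_db, 40)
})

test_that("filter specifications are validated", {
  expect_error(filter_spec(low_hz = 0), "low_hz")
  expect_error(filter_spec(low_hz = 10, high_hz = 5), "high_hz")
  expect_error(filter_spec(order = 401), "order")
  expect_error(bandpass_fir(rnorm(100), filter_spec(0.5, 60), fs = 100),
               "Nyquist")
})

test_that("segmentation yields one 6000-sample segment per labeled minute", {
  rec <- generate_record(tiny_synth(minutes = 10L, apnea_fraction = 0.3), 0)
  ss <- segment_record(rec)
  expect_identical(nrow(ss$x) + nrow(ss$flagged), 10L)
  expect_identical(ncol(ss$x), 6000L)
  expect_lt(max(abs(rowMeans(ss$x))), 1e-9)
  expect_identical(ss$label, rec$minute_labels[ss$minute + 1L])

  empty <- rec
  empty$minute_labels <- character(0)
  ss0 <- segment_record(structure(empty, class = "ecg_record"))
  expect_identical(nrow(ss0$x), 0L)
})

test_that("noisy minutes are excluded with reasons, conserving the count", {
  rec <- generate_record(tiny_synth(minutes = 8L, apnea_fraction = 0.5,
                                    seed = 3L), 0)
  # inject a large movement artifact into minute 3 (0-based)
  spike_at <- 3L * 6000L + 2000L
  rec$samples[spike_at:(spike_at + 50L)] <- 50 * max(abs(rec$samples))
  ss <- segment_record(rec)
  expect_identical(nrow(ss$x) + nrow(ss$flagged), 8L)
  expect_true(3L %in% ss$flagged$minute)
  expect_false(3L %in% ss$minute)
  kept_all <- segment_record(rec, exclude_noisy = FALSE)
  expect_identical(nrow(kept_all$x), 8L)
})

test_that("quality rules fire for flatline, clipping and bursts only", {
  fs <- 100
  flat <- flag_noisy(rep(0, 6000), fs)
  expect_true(flat$flagged)
  expect_identical(flat$reason, "flatline")

  rec <- generate_record(tiny_synth(minutes = 2L, apnea_fraction = 0,
                                    seed = 4L), 0)
  ss <- segment_record(rec, exclude_noisy = FALSE)
  clean <- flag_noisy(ss$x[1, ], fs, record_mad = mad(ss$x))
  expect_false(clean$flagged)

  seg <- ss$x[1, ]
  seg[100] <- 50 * max(abs(seg))
  burst <- flag_noisy(seg, fs, record_mad = mad(ss$x))
  expect_true(burst$flagged)
  expect_identical(burst$reason, "amplitude burst")

  clipped <- pmin(pmax(ss$x[1, ] * 50, -1), 1)
  cl <- flag_noisy(clipped, fs, record_mad = mad(ss$x))
  expect_true(cl$flagged)
})
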