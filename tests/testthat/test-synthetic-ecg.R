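test_that("minute labels follow the configured apnea fraction exactly", {
  cfg <- tiny_synth(minutes = 10L, apnea_fraction = 0.4)
  rec <- generate_record(cfg, 0)
  expect_length(rec$minute_labels, 10L)
  expect_identical(sum(rec$minute_labels == "A"), 4L)
  expect_identical(sum(rec$minute_labels == "N"), 6L)

  all_normal <- generate_record(tiny_synth(minutes = 12L, apnea_fraction = 0), 0)
  expect_true(all(all_normal$minute_labels == "N"))
})

test_that("generation is bit-reproducible given (seed, subject_index)", {
  cfg <- tiny_synth()
  a <- generate_record(cfg, 1)
  b <- generate_record(cfg, 1)
  expect_identical(a$samples, b$samples)
  expect_identical(a$minute_labels, b$minute_labels)
  c <- generate_record(cfg, 0)
  expect_false(identical(a$samples, c$samples))
})

test_that("noiseless normal minutes have the configured heart rate", {
  cfg <- tiny_synth(minutes = 4L, apnea_fraction = 0, noise_sd = 0,
                    baseline_wander_amp = 0)
  rec <- generate_record(cfg, 0)
  rr <- rr_intervals(rec$samples, rec$fs)
  expect_gt(length(rr), 200)
  expect_lt(abs(mean(rr) - 60 / cfg$hr_normal_bpm) / (60 / cfg$hr_normal_bpm),
            0.01)
})

test_that("dataset pooling matches the requested class imbalance", {
  frac <- 6019 / (6019 + 9160)
  cfg <- synth_config(n_subjects = 3L, minutes_per_subject = 60L,
                      apnea_fraction = frac, seed = 5L)
  recs <- generate_dataset(cfg)
  expect_length(recs, 3L)
  expect_length(unique(vapply(recs, `[[`, "", "subject_id")), 3L)
  labels <- unlist(lapply(recs, `[[`, "minute_labels"))
  expect_lt(abs(mean(labels == "A") - frac), 0.02)
})

test_that("apnea minutes carry more RR variability than normal minutes", {
  cfg <- tiny_synth(minutes = 10L, apnea_fraction = 0.5, noise_sd = 0,
                    baseline_wander_amp = 0, seed = 9L)
  rec <- generate_record(cfg, 0)
  seg_len <- 60 * rec$fs
  rr_sd <- function(m) {
    seg <- rec$samples[((m - 1) * seg_len + 1):(m * seg_len)]
    sd(rr_intervals(seg, rec$fs))
  }
  apnea_sd <- vapply(which(rec$minute_labels == "A"), rr_sd, 0)
  normal_sd <- vapply(which(rec$minute_labels == "N"), rr_sd, 0)
  expect_gt(min(apnea_sd), max(normal_sd))
})

test_that("apnea amplitude envelope oscillates with the configured period", {
  cfg <- tiny_synth(n_subjects = 1L, minutes = 5L, apnea_fraction = 1,
                    noise_sd = 0, baseline_wander_amp = 0, seed = 2L)
  rec <- generate_record(cfg, 0)
  pk <- apneamodes:::find_peaks(rec$samples, 0.5 * max(rec$samples),
                                as.integer(0.3 * rec$fs))
  tp <- pk / rec$fs
  hp <- rec$samples[pk] - mean(rec$samples[pk])
  periods <- seq(20, 80, by = 0.5)
  power <- vapply(periods, function(T) abs(sum(hp * exp(-2i * pi * tp / T))), 0)
  expect_lt(abs(periods[which.max(power)] - cfg$apnea_cycle_s),
            0.1 * cfg$apnea_cycle_s)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synth_config(apnea_fraction = 1.4), "apnea_fraction")
  expect_error(synth_config(hr_apnea_low_bpm = 80, hr_normal_bpm = 70),
               "hr_apnea_low_bpm")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
  expect_error(generate_record(tiny_synth(n_subjects = 2L), 2),
               "subject_index")
})
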