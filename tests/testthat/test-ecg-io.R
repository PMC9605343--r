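test_that("CSV round-trip is lossless", {
  rec <- generate_record(tiny_synth(minutes = 3L), 0)
  base <- file.path(withr::local_tempdir(), rec$subject_id)
  write_ecg(rec, base, format = "csv")
  back <- read_ecg(base, format = "csv")
  expect_equal(back$samples, rec$samples)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$minute_labels, rec$minute_labels)
  expect_identical(back$subject_id, rec$subject_id)
})

test_that("WFDB round-trip is exact to the quantization bound", {
  rec <- generate_record(tiny_synth(minutes = 3L), 1)
  base <- file.path(withr::local_tempdir(), rec$subject_id)
  gain <- 200
  files <- write_ecg(rec, base, format = "wfdb", gain = gain)
  expect_setequal(tools::file_ext(files), c("hea", "dat", "apn"))
  back <- read_ecg(base, format = "wfdb")
  expect_lte(max(abs(back$samples - rec$samples)), 1 / (2 * gain) + 1e-12)
  expect_identical(back$minute_labels, rec$minute_labels)
  expect_identical(back$fs, rec$fs)
})

test_that("annotation text parses one label character per minute", {
  f <- withr::local_tempfile(lines = "ANA")
  expect_identical(apneamodes:::parse_annotations(f), c("A", "N", "A"))
  f2 <- withr::local_tempfile(lines = c("A", "N", "N"))
  expect_identical(apneamodes:::parse_annotations(f2), c("A", "N", "N"))
  f3 <- withr::local_tempfile(lines = "ANX")
  expect_error(apneamodes:::parse_annotations(f3), "X")
})

test_that("records without labels or with misaligned labels are rejected", {
  rec <- generate_record(tiny_synth(minutes = 2L), 0)
  base <- file.path(withr::local_tempdir(), "r")
  write_ecg(rec, base, format = "wfdb")
  unlink(paste0(base, ".apn"))
  expect_error(read_ecg(base, format = "wfdb"), "annotation")

  # CSV sidecar claiming 3 labeled minutes over too few samples
  base2 <- file.path(withr::local_tempdir(), "r2")
  write.csv(data.frame(sample_index = 0:999, value = rnorm(1000)),
            paste0(base2, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(subject_id = "r2", fs = 100,
                            minute_labels = c("A", "N", "A")),
                       paste0(base2, ".json"), auto_unbox = TRUE)
  expect_error(read_ecg(base2, format = "csv"), "fewer than")
})

test_that("degenerate writes and headers error clearly", {
  rec <- generate_record(tiny_synth(minutes = 2L), 0)
  bad <- rec
  bad$samples <- numeric(0)
  expect_error(write_ecg(structure(bad, class = "ecg_record"),
                         tempfile(), "csv"), "empty")
  base <- file.path(withr::local_tempdir(), "r3")
  write_ecg(rec, base, format = "wfdb")
  hea <- readLines(paste0(base, ".hea"))
  hea[1] <- sub(" 100 ", " 0 ", hea[1], fixed = TRUE)
  writeLines(hea, paste0(base, ".hea"))
  expect_error(read_ecg(base, format = "wfdb"), "sampling rate")
})
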