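test_that("envelope mean cancels for a symmetric oscillation", {
  t <- (0:5999) / 100
  y <- sin(2 * pi * t)
  m <- envelope_mean(y)
  expect_lt(max(abs(m[interior(6000)])), 0.05)
  m5 <- envelope_mean(y + 5)
  expect_lt(max(abs(m5[interior(6000)] - 5)), 0.05)
  expect_null(envelope_mean(seq(0, 1, length.out = 100)))
})

test_that("sifting returns a near-pure tone quickly and respects fixed points", {
  t <- (0:5999) / 100
  y <- sin(2 * pi * t)
  s <- sift(y)
  expect_lte(s$iterations, 3L)
  idx <- interior(6000)
  expect_gte(cor(s$imf[idx], y[idx]), 0.99)

  # a signal already satisfying both IMF requirements is returned unchanged
  s2 <- sift(s$imf)
  expect_identical(s2$iterations, 1L)
  expect_identical(s2$imf, s$imf)
})

test_that("a two-tone mixture separates into its components", {
  tt <- two_tone()
  d <- emd_decompose(tt$mix, max_imfs = 20)
  expect_gte(length(d$imfs), 2L)
  idx <- interior(length(tt$mix))
  expect_gte(cor(d$imfs[[1]][idx], tt$fast[idx]), 0.95)
  expect_gte(cor(d$imfs[[2]][idx], tt$slow[idx]), 0.90)
})

test_that("decomposition telescopes back to the input exactly", {
  set.seed(11)
  for (n in c(300L, 2000L)) {
    y <- rnorm(n)
    d <- emd_decompose(y, max_imfs = 20)
    recon <- Reduce(`+`, d$imfs, accumulate = FALSE) + d$residue
    expect_lt(max(abs(y - recon)), 1e-9 * max(abs(y)))
  }
  const <- emd_decompose(rep(2.5, 100))
  expect_length(const$imfs, 0L)
  expect_identical(const$residue, rep(2.5, 100))
  expect_error(emd_decompose(rnorm(10)), "length")
})

test_that("extracted IMFs satisfy the extrema/zero-crossing requirement", {
  set.seed(21)
  for (rep_i in 1:10) {
    y <- rnorm(1500)
    d <- emd_decompose(y, max_imfs = 20, stop = sift_config(max_sift = 500))
    expect_true(all(vapply(d$imfs, imf_valid, logical(1))))
    expect_lte(count_extrema(d$residue), 2L)
  }
})

test_that("mean zero-crossing rate is non-increasing across IMFs", {
  t <- (0:5999) / 100
  y <- sin(2 * pi * 8 * t) + sin(2 * pi * 2 * t) + sin(2 * pi * 0.4 * t)
  d <- emd_decompose(y, max_imfs = 20)
  zcr <- vapply(d$imfs, apneamodes:::count_zero_crossings, integer(1))
  expect_true(all(diff(zcr) <= 0))
})

test_that("IMF combination features are exact elementwise sums", {
  imfset <- structure(list(
    imfs = list(c(1, 1), c(2, 2), c(3, 3)), residue = c(0, 0),
    sift_counts = c(1L, 1L, 1L), converged = rep(TRUE, 3), n = 2L),
    class = "imf_set")
  f <- build_imf_features(imfset)
  expect_equal(f$IMF1, c(1, 1))
  expect_equal(f$IMF2, c(2, 2))
  expect_equal(f$IMF12, c(3, 3))
  expect_equal(f$IMF123, c(6, 6))

  only1 <- build_imf_features(imfset, kinds = "IMF1")
  expect_named(only1, "IMF1")

  two <- imfset
  two$imfs <- two$imfs[1:2]
  expect_error(build_imf_features(two, kinds = "IMF123", segment_id = "s01:4"),
               "IMF123.*s01:4")
})

test_that("plateaus collapse to single extrema and zeros count once", {
  y <- c(0, 1, 2, 2, 2, 1, 0, -1, -2, -1, 0, 1)
  ex <- apneamodes:::find_extrema(y)
  expect_identical(ex$maxima, 4L)  # midpoint of the flat top
  expect_identical(ex$minima, 9L)
  expect_identical(apneamodes:::count_zero_crossings(c(1, 0, -1, 0, 0, 1)), 2L)
  expect_identical(apneamodes:::count_zero_crossings(rep(0, 5)), 0L)
})
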