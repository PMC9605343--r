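test_that("the selection threshold is 2% of the maximum weight", {
  r <- nca_select(c(a = 1.0, b = 0.5, c = 0.01))
  expect_equal(r$threshold, 0.02)
  expect_identical(unname(r$selected_columns), c(1L, 2L))

  r2 <- nca_select(c(0.02, 0.02))
  expect_equal(r2$threshold, 4e-4)
  expect_identical(unname(r2$selected_columns), c(1L, 2L))

  expect_warning(r0 <- nca_select(c(0, 0, 0)), "zero")
  expect_length(r0$selected_columns, 0L)
})

test_that("selected IMFs are those with any selected statistic column", {
  w <- c(i1_mean = 0.9, i1_sd = 0.001, i2_mean = 0.005, i4_var = 0.01)
  r <- nca_select(w)
  expect_identical(r$selected_imfs, 1L)
  w2 <- c(i1_mean = 0.5, i3_sd = 0.4, i6_var = 0.001)
  expect_identical(nca_select(w2)$selected_imfs, c(1L, 3L))
})

test_that("duplicated columns receive equal weights", {
  tab <- simulate_feature_table(n = 200, seed = 4)
  x <- cbind(tab$x[, 1], tab$x)
  w <- fit_nca(x, tab$y, lambda = 0.05, seed = 2)
  expect_lt(abs(w[1] - w[2]) / max(w[1], w[2], 1e-12), 0.05)
})

test_that("informative columns dominate and over-regularization kills weights", {
  tab <- simulate_feature_table(n = 250, seed = 7)
  w <- fit_nca(tab$x, tab$y, lambda = 0.05, seed = 7)
  expect_true(all(rank(-w)[tab$informative] <= 5))
  w_big <- fit_nca(tab$x, tab$y, lambda = 1, seed = 7)
  expect_lt(max(w_big), max(w))
})

test_that("weights are invariant to raw column scaling", {
  tab <- simulate_feature_table(n = 200, seed = 4)
  w <- fit_nca(tab$x, tab$y, lambda = 0.05, seed = 1)
  x2 <- tab$x
  x2[, 2] <- x2[, 2] * 500
  w2 <- fit_nca(x2, tab$y, lambda = 0.05, seed = 1)
  expect_equal(w, w2, tolerance = 1e-8)
})

test_that("lambda tuning minimizes held-out 1-NN loss deterministically", {
  tab <- simulate_feature_table(n = 120, n_informative = 2, n_noise = 4,
                                seed = 3)
  one <- tune_nca_lambda(tab$x, tab$y, lambda_grid = 0.05, folds = 4,
                         seed = 1, max_iter = 40)
  expect_identical(one$best_lambda, 0.05)

  tn <- tune_nca_lambda(tab$x, tab$y, lambda_grid = c(0.01, 0.1, 1),
                        folds = 4, seed = 1, max_iter = 40)
  tn2 <- tune_nca_lambda(tab$x, tab$y, lambda_grid = c(0.01, 0.1, 1),
                         folds = 4, seed = 1, max_iter = 40)
  expect_identical(tn$loss_per_lambda, tn2$loss_per_lambda)
  expect_lt(tn$loss_per_lambda[which(tn$lambda_grid == tn$best_lambda)],
            tn$loss_per_lambda[3])
})

test_that("the feature table summarizes IMFs with zeros for absent modes", {
  recs <- generate_dataset(tiny_synth(n_subjects = 1L, minutes = 4L))
  ss <- segment_record(recs[[1]])
  sets <- lapply(seq_len(nrow(ss$x)), function(i) {
    emd_decompose(ss$x[i, ], max_imfs = 2)
  })
  tab <- imf_feature_table(sets, ss$label, n_imfs = 4)
  expect_identical(dim(tab$x), c(nrow(ss$x), 12L))
  expect_identical(tab$imf_of_column, rep(1:4, each = 3L))
  expect_true(all(tab$x[, 10:12] == 0))  # IMF4 never extracted
  expect_false(anyNA(tab$x))
})
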