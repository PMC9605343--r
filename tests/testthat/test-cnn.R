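test_that("the reference architecture reproduces the pooled length chain", {
  spec <- cnn_spec()
  expect_identical(spec$block_lengths,
                   c(3000L, 1500L, 750L, 375L, 187L, 93L, 46L, 23L))
  reduced <- cnn_spec(n_blocks = 4, filters = 8)
  expect_identical(reduced$block_lengths, c(3000L, 1500L, 750L, 375L))
  expect_error(cnn_spec(input_len = 16, n_blocks = 8), "too short")
})

test_that("parameter counts match the layer arithmetic", {
  m <- cnn_build(cnn_spec(), seed = 1)
  cnt <- cnn_count_params(m)
  expect_equal(unname(cnt["conv1"]), 45 * (32 * 1) + 45)
  expect_equal(unname(cnt["conv1_bn"]), 2 * 45)
  expect_equal(unname(cnt["conv2"]), 45 * (32 * 45) + 45)
  expect_equal(unname(cnt["fc1"]), 23 * 45 * 512 + 512)
  expect_equal(unname(cnt["out"]), 512 * 2 + 2)
})

test_that("softmax outputs are proper probabilities, even on zero input", {
  m <- cnn_build(cnn_spec(), seed = 2)
  p <- cnn_predict_proba(m, matrix(0, 1, 6000))
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(rowSums(p)), 1, tolerance = 1e-6)
  expect_error(cnn_predict_proba(m, matrix(0, 1, 500)), "6000")
})

test_that("inference is deterministic and batch-invariant", {
  spec <- cnn_spec(input_len = 512, n_blocks = 3, filters = 4,
                   fc_blocks = 1, fc_units = 16)
  m1 <- cnn_build(spec, seed = 7)
  m2 <- cnn_build(spec, seed = 7)
  set.seed(3)
  X <- matrix(rnorm(8 * 512), 8, 512)
  expect_identical(cnn_predict_proba(m1, X), cnn_predict_proba(m2, X))

  p_all <- cnn_predict_proba(m1, X)
  p_one <- cnn_predict_proba(m1, X[3, , drop = FALSE])
  expect_equal(p_all[3, ], p_one[1, ], tolerance = 1e-5)
})

test_that("dropout is active only in training mode", {
  spec <- cnn_spec(input_len = 256, n_blocks = 2, filters = 4,
                   fc_blocks = 1, fc_units = 16, dropout = 0.5)
  m <- cnn_build(spec, seed = 1)
  set.seed(5)
  X <- matrix(rnorm(4 * 256), 4, 256)
  set.seed(10)
  tr1 <- apneamodes:::cnn_forward(m, X, training = TRUE)$probs
  set.seed(11)
  tr2 <- apneamodes:::cnn_forward(m, X, training = TRUE)$probs
  expect_false(identical(tr1, tr2))
  ev1 <- apneamodes:::cnn_forward(m, X, training = FALSE)$probs
  ev2 <- apneamodes:::cnn_forward(m, X, training = FALSE)$probs
  expect_identical(ev1, ev2)
})

test_that("training separates a linearly separable toy and reproduces", {
  spec <- cnn_spec(input_len = 1000, n_blocks = 4, filters = 8,
                   kernel_size = 32, fc_blocks = 1, fc_units = 32)
  X <- rbind(matrix(-1, 50, 1000), matrix(1, 50, 1000))
  y <- c(rep("N", 50), rep("A", 50))
  cfg <- cnn_train_config(epochs = 10, batch_size = 64, learning_rate = 3e-3,
                          seed = 2)
  m <- cnn_train(cnn_build(spec, seed = 1), X, y, cfg)
  expect_gte(tail(m$history$accuracy, 1), 0.95)
  expect_lt(tail(m$history$loss, 1), m$history$loss[1])
  p <- cnn_predict_proba(m, X)
  expect_gte(mean((p[, "apnea"] >= 0.5) == (y == "A")), 0.95)

  m2 <- cnn_train(cnn_build(spec, seed = 1), X, y, cfg)
  expect_identical(m$history$loss, m2$history$loss)
})

test_that("degenerate training requests error out", {
  spec <- cnn_spec(input_len = 64, n_blocks = 2, filters = 2,
                   fc_blocks = 1, fc_units = 4)
  m <- cnn_build(spec, 1)
  X <- matrix(rnorm(6 * 64), 6, 64)
  expect_error(cnn_train_config(epochs = 0), "epochs")
  expect_error(cnn_train(m, X, rep("A", 6),
                         cnn_train_config(epochs = 1, batch_size = 4)),
               "single class")
})
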