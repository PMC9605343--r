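test_that("k-fold splits are disjoint, exhaustive, and balanced", {
  for (n in c(10L, 23L, 57L)) {
    folds <- kfold_split(n, k = 5, seed = 1, stratified = FALSE)
    expect_length(folds, 5L)
    expect_identical(sort(unlist(folds)), seq_len(n))
    sizes <- lengths(folds)
    expect_lte(diff(range(sizes)), 1L)
  }
  expect_identical(lengths(kfold_split(10L, k = 5, seed = 2)), rep(2L, 5))
  expect_error(kfold_split(3L, k = 5), "smaller")
})

test_that("stratified folds preserve the class ratio within one sample", {
  y <- c(rep("A", 8), rep("N", 12))
  folds <- kfold_split(y, k = 4, seed = 3, stratified = TRUE)
  for (f in folds) {
    expect_identical(sum(y[f] == "A"), 2L)
    expect_identical(sum(y[f] == "N"), 3L)
  }
  expect_identical(kfold_split(y, k = 4, seed = 3),
                   kfold_split(y, k = 4, seed = 3))
})

test_that("leave-one-subject-out partitions segments by subject exactly", {
  subj <- rep(c("s1", "s2", "s3"), times = c(4, 6, 5))
  splits <- loso_split(subj)
  expect_length(splits, 3L)
  test_union <- integer(0)
  for (sp in splits) {
    expect_setequal(unique(subj[sp$test]), sp$subject)
    expect_false(sp$subject %in% subj[sp$train])
    expect_length(intersect(sp$train, sp$test), 0L)
    test_union <- c(test_union, sp$test)
  }
  expect_identical(sort(test_union), seq_along(subj))

  two <- loso_split(c("a", "a", "b"))
  expect_identical(two[[1]]$test, two[[2]]$train)
  expect_error(loso_split(rep("only", 5)), "2 subjects")
})

test_that("metrics follow the confusion-count formulas exactly", {
  y <- c(rep(1, 100), rep(0, 100))
  p <- c(rep(1, 90), rep(0, 10), rep(1, 20), rep(0, 80))
  r <- score_predictions(y, p)
  expect_identical(unname(r$counts), c(90L, 20L, 80L, 10L))
  expect_equal(r$accuracy, 85)
  expect_equal(r$sensitivity, 90)
  expect_equal(r$specificity, 80)
  expect_equal(r$youden_j, 0.70)
})

test_that("AUC is 1 for perfect scores, 0.5 under a permutation null", {
  y <- rep(c(1, 0), 50)
  expect_equal(score_predictions(y, y)$auc, 1.0)
  set.seed(123)
  y2 <- sample(rep(0:1, 5000))
  p2 <- runif(10000)
  expect_lt(abs(score_predictions(y2, p2)$auc - 0.5), 0.02)
})

test_that("AUC matches pROC and survives monotone transformation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(300, 1, 0.4)
  p <- plogis(rnorm(300) + y)
  r <- score_predictions(y, p)
  ref <- as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(r$auc, ref, tolerance = 1e-10)
  r2 <- score_predictions(y, plogis(qlogis(p) * 2))
  expect_equal(r2$auc, r$auc, tolerance = 1e-10)
})

test_that("single-class truths yield NaN metrics with a warning", {
  set.seed(2)
  p <- runif(10)
  expect_warning(r <- score_predictions(rep(1, 10), p), "single-class")
  expect_true(is.nan(r$specificity))
  expect_true(is.nan(r$auc))
  expect_equal(r$sensitivity, 100 * mean(p >= 0.5))
  expect_true(is.nan(r$youden_j))
})

test_that("accuracy decomposes into class-weighted sensitivity/specificity", {
  set.seed(9)
  for (i in 1:20) {
    cts <- rmultinom(1, 200, c(0.3, 0.2, 0.3, 0.2))[, 1] + 1L
    names(cts) <- c("TP", "FP", "TN", "FN")
    y <- c(rep(1, cts["TP"] + cts["FN"]), rep(0, cts["TN"] + cts["FP"]))
    p <- c(rep(1, cts["TP"]), rep(0, cts["FN"]), rep(0, cts["TN"]),
           rep(1, cts["FP"]))
    r <- score_predictions(y, p)
    pos <- unname(cts["TP"] + cts["FN"])
    neg <- unname(cts["TN"] + cts["FP"])
    expect_equal(r$accuracy,
                 (r$sensitivity * pos + r$specificity * neg) / (pos + neg))
  }
})

test_that("Youden selection picks the highest J with documented tie-breaks", {
  mk <- function(j, acc) {
    structure(list(youden_j = j, accuracy = acc), class = "eval_report")
  }
  best <- youden_select(list(mk(0.70, 80), mk(0.85, 90), mk(0.60, 95)))
  expect_equal(best$youden_j, 0.85)
  expect_identical(attr(best, "which"), 2L)

  # sensitivity 94.9% and specificity 92.7% give J = 0.876
  r <- structure(list(sensitivity = 94.9, specificity = 92.7), class = "list")
  expect_equal((r$sensitivity + r$specificity) / 100 - 1, 0.876)

  tie <- youden_select(list(mk(0.8, 85), mk(0.8, 91)))
  expect_identical(attr(tie, "which"), 2L)
  single <- youden_select(list(mk(0.5, 70)))
  expect_equal(single$youden_j, 0.5)
})

test_that("aggregation averages metrics or pools counts consistently", {
  mk <- function(acc, counts) {
    structure(list(accuracy = acc, sensitivity = acc, specificity = acc,
                   auc = acc / 100, youden_j = acc / 50 - 1, counts = counts),
              class = "eval_report")
  }
  two <- list(mk(80, c(TP = 8, FP = 2, TN = 8, FN = 2)),
              mk(90, c(TP = 9, FP = 1, TN = 9, FN = 1)))
  m <- aggregate_reports(two, mode = "mean")
  expect_equal(m$metrics$accuracy, 85)

  # with equal per-unit n, pooled counts give the same accuracy as the mean
  set.seed(4)
  reps <- lapply(1:5, function(i) {
    y <- rep(c(1, 0), each = 50)
    p <- as.numeric(runif(100) < 0.5)
    suppressWarnings(score_predictions(y, p))
  })
  expect_equal(aggregate_reports(reps, "pooled")$metrics$accuracy,
               aggregate_reports(reps, "mean")$metrics$accuracy)

  with_nan <- list(
    structure(list(accuracy = 80, sensitivity = NaN, specificity = 90,
                   auc = NaN, youden_j = NaN, counts = c(TP = 0, FP = 1, TN = 9, FN = 0)),
              class = "eval_report"),
    structure(list(accuracy = 90, sensitivity = 88, specificity = 92,
                   auc = 0.9, youden_j = 0.8, counts = c(TP = 5, FP = 1, TN = 4, FN = 0)),
              class = "eval_report"))
  agg <- aggregate_reports(with_nan, mode = "mean")
  expect_equal(agg$metrics$sensitivity, 88)
  expect_identical(agg$n_dropped$sensitivity, 1L)
})
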