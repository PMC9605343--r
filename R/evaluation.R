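#' Cross-validation splits and classification scoring
#'
#' Apnea is the positive class throughout: TP counts apnea minutes predicted
#' apnea. Accuracy, sensitivity and specificity are reported in percent;
#' Youden's J = (sensitivity + specificity)/100 - 1 is the model-selection
#' statistic.
#'
#' @name evaluation
NULL

#' Random k-fold split of segment indices
#'
#' Stratified mode deals each class round-robin across folds (continuing a
#' global pointer so overall fold sizes differ by at most one while the class
#' ratio per fold is preserved within one sample).
#'
#' @param y Label vector (its length defines `n`), or a single integer `n`
#'   for unstratified splitting.
#' @param k Number of folds.
#' @param seed Seed.
#' @param stratified Preserve class ratios per fold.
#' @return List of `k` disjoint index vectors whose union is `1..n`.
#' @export
kfold_split <- function(y, k = 5L, seed = 1L, stratified = TRUE) {
  if (length(y) == 1L && is.numeric(y)) y <- rep("x", y)
  n <- length(y)
  k <- as.integer(k)
  if (n < k) stop(sprintf("n = %d is smaller than k = %d", n, k), call. = FALSE)
  with_seed(seed, {
    folds <- vector("list", k)
    if (stratified) {
      pointer <- 0L
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        assign_to <- ((pointer + seq_along(idx) - 1L) %% k) + 1L
        pointer <- (pointer + length(idx)) %% k
        for (f in seq_len(k)) {
          folds[[f]] <- c(folds[[f]], idx[assign_to == f])
        }
      }
    } else {
      idx <- sample(n)
      assign_to <- ((seq_len(n) - 1L) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- idx[assign_to == f]
    }
    lapply(folds, sort)
  })
}

#' Leave-one-subject-out split
#'
#' @param subject Character vector: subject id of every segment.
#' @return List with one element per unique subject: `list(subject, train,
#'   test)` index vectors; the test set is exactly that subject's segments.
#' @export
loso_split <- function(subject) {
  subjects <- unique(subject)
  if (length(subjects) < 2L) {
    stop("leave-one-subject-out needs at least 2 subjects", call. = FALSE)
  }
  lapply(subjects, function(s) {
    test <- which(subject == s)
    list(subject = s, train = setdiff(seq_along(subject), test), test = test)
  })
}

#' Score predicted apnea probabilities against true labels
#'
#' @param y_true Labels: "A"/"N", or 0/1 with 1 = apnea.
#' @param y_prob Predicted apnea probability per segment, in `[0, 1]`.
#' @param threshold Probability cut for the hard label.
#' @return An `eval_report`: confusion counts, `accuracy`, `sensitivity`,
#'   `specificity` (percent; `NaN` with a warning when a class is absent),
#'   `auc` (trapezoidal over the ROC), `youden_j`, and the `roc` points.
#' @export
score_predictions <- function(y_true, y_prob, threshold = 0.5) {
  y <- as_apnea_indicator(y_true)
  if (length(y) != length(y_prob)) {
    stop("`y_true` and `y_prob` lengths differ", call. = FALSE)
  }
  if (any(y_prob < 0 | y_prob > 1)) {
    stop("`y_prob` must lie in [0, 1]", call. = FALSE)
  }
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  pos <- tp + fn
  neg <- tn + fp
  if (pos == 0L || neg == 0L) {
    warning("single-class y_true: sensitivity/specificity/AUC partly undefined")
  }
  sens <- if (pos > 0L) 100 * tp / pos else NaN
  spec <- if (neg > 0L) 100 * tn / neg else NaN
  acc <- 100 * (tp + tn) / length(y)
  roc <- roc_points(y, y_prob)
  auc <- if (pos > 0L && neg > 0L) trapezoid_auc(roc) else NaN
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    accuracy = acc, sensitivity = sens, specificity = spec,
    auc = auc, youden_j = (sens + spec) / 100 - 1,
    roc = roc, n = length(y), threshold = threshold),
    class = "eval_report")
}

as_apnea_indicator <- function(y_true) {
  if (is.character(y_true) || is.factor(y_true)) {
    as.integer(as.character(y_true) == "A")
  } else {
    as.integer(y_true)
  }
}

# ROC over all distinct thresholds; tied probabilities cross simultaneously.
roc_points <- function(y, p) {
  ord <- order(p, decreasing = TRUE)
  y <- y[ord]
  p <- p[ord]
  pos <- sum(y == 1L)
  neg <- sum(y == 0L)
  grp <- cumsum(!duplicated(p))
  tp <- cumsum(y == 1L)
  fp <- cumsum(y == 0L)
  last <- which(!duplicated(grp, fromLast = TRUE))
  data.frame(
    threshold = c(Inf, p[last]),
    tpr = c(0, if (pos > 0) tp[last] / pos else rep(0, length(last))),
    fpr = c(0, if (neg > 0) fp[last] / neg else rep(0, length(last))))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  acc %.1f%%  sens %.1f%%  spec %.1f%%  AUC %.4f  J %.3f\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$auc, x$youden_j))
  invisible(x)
}

#' Select the best report by Youden's index
#'
#' Ties are broken by higher accuracy, then first occurrence.
#'
#' @param reports List of `eval_report`s.
#' @return The winning report, with attribute `"which"`.
#' @export
youden_select <- function(reports) {
  if (!length(reports)) stop("no reports to select from", call. = FALSE)
  j <- vapply(reports, function(r) r$youden_j, numeric(1))
  acc <- vapply(reports, function(r) r$accuracy, numeric(1))
  best <- order(-j, -acc)[1L]
  out <- reports[[best]]
  attr(out, "which") <- best
  out
}

#' Aggregate per-fold or per-subject reports
#'
#' `"mean"` averages each metric across units, ignoring `NaN` entries (their
#' count is recorded in `n_dropped`); `"pooled"` sums the confusion counts
#' and recomputes accuracy/sensitivity/specificity/J (AUC is averaged, since
#' it is not a function of pooled counts).
#'
#' @param reports List of `eval_report`s.
#' @param mode `"mean"` or `"pooled"`.
#' @return List of class `eval_summary`.
#' @export
aggregate_reports <- function(reports, mode = c("mean", "pooled")) {
  mode <- match.arg(mode)
  if (!length(reports)) stop("no reports to aggregate", call. = FALSE)
  metrics <- c("accuracy", "sensitivity", "specificity", "auc", "youden_j")
  vals <- sapply(metrics, function(m) {
    vapply(reports, function(r) r[[m]], numeric(1))
  })
  vals <- matrix(vals, nrow = length(reports),
                 dimnames = list(NULL, metrics))
  if (mode == "mean") {
    out <- colMeans(vals, na.rm = TRUE)
    dropped <- as.integer(colSums(is.na(vals)))
    names(dropped) <- metrics
  } else {
    cts <- Reduce(`+`, lapply(reports, `[[`, "counts"))
    acc <- 100 * (cts["TP"] + cts["TN"]) / sum(cts)
    sens <- 100 * cts[["TP"]] / (cts[["TP"]] + cts[["FN"]])
    spec <- 100 * cts[["TN"]] / (cts[["TN"]] + cts[["FP"]])
    out <- c(accuracy = unname(acc), sensitivity = sens, specificity = spec,
             auc = mean(vals[, "auc"], na.rm = TRUE),
             youden_j = (sens + spec) / 100 - 1)
    dropped <- c(rep(0L, 3L), sum(is.na(vals[, "auc"])), 0L)
    names(dropped) <- metrics
  }
  structure(list(mode = mode, metrics = as.list(out),
                 n_units = length(reports), n_dropped = as.list(dropped)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<eval_summary> %s over %d units: acc %.1f%%  sens %.1f%%  spec %.1f%%  AUC %.4f  J %.3f\n",
    x$mode, x$n_units, m$accuracy, m$sensitivity, m$specificity, m$auc,
    m$youden_j))
  invisible(x)
}
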