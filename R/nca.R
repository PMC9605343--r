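#' Neighborhood component analysis feature selection
#'
#' NCA learns one nonnegative weight per feature by maximizing the expected
#' leave-one-out correct-classification probability of a stochastic nearest
#' neighbor rule under the squared weighted distance
#' `d_ij = sum_r w_r^2 (x_ir - x_jr)^2`, minus an L2 penalty
#' `lambda * sum_r w_r^2`. Features whose weight exceeds the threshold
#' `T = tau * max(w)` (with `tau = 0.02`) are selected; an IMF is selected
#' when any of its summary-statistic columns is.
#'
#' @name nca_select
NULL

#' Summary-statistic feature table of an IMF decomposition
#'
#' One row per segment, columns `i<j>_mean`, `i<j>_sd`, `i<j>_var` for IMF
#' indices `j = 1..n_imfs`. Segments whose decomposition produced fewer than
#' `n_imfs` IMFs contribute zeros for the missing modes (an absent mode is an
#' identically-zero component).
#'
#' @param imf_sets List of `imf_set` objects, one per segment.
#' @param labels Character vector of segment labels ("A"/"N").
#' @param n_imfs Number of candidate IMFs to summarize.
#' @return List of class `feature_table` with `x` (numeric matrix), `y`
#'   (labels), `imf_of_column` (integer map column -> IMF index).
#' @export
imf_feature_table <- function(imf_sets, labels, n_imfs = 6L) {
  stopifnot(length(imf_sets) == length(labels))
  n_imfs <- as.integer(n_imfs)
  stats_of <- function(v) c(mean = mean(v), sd = sd(v), var = var(v))
  rows <- t(vapply(imf_sets, function(s) {
    unlist(lapply(seq_len(n_imfs), function(j) {
      if (length(s$imfs) >= j) stats_of(s$imfs[[j]]) else c(mean = 0, sd = 0, var = 0)
    }))
  }, numeric(3L * n_imfs)))
  colnames(rows) <- as.vector(vapply(seq_len(n_imfs), function(j) {
    paste0("i", j, "_", c("mean", "sd", "var"))
  }, character(3L)))
  structure(list(x = rows, y = as.character(labels),
                 imf_of_column = rep(seq_len(n_imfs), each = 3L)),
            class = "feature_table")
}

# Standardize columns to zero mean / unit variance (constant columns stay 0).
standardize_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0] <- 1
  scale(x, center = mu, scale = sdv)
}

#' Fit NCA feature weights
#'
#' Gradient ascent on the regularized NCA objective with adaptive step size
#' (growing on acceptance, halving on rejection), starting from `w = 1`.
#' Columns are standardized internally. Weights are reported as `|w|`.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Class labels (any vector; compared with `==`).
#' @param lambda Regularization strength (>= 0).
#' @param seed Seed (the optimizer is deterministic; the seed fixes any
#'   tie-breaking and keeps the interface uniform).
#' @param max_iter Maximum ascent iterations.
#' @param tol Relative objective-change convergence tolerance.
#' @return Named nonnegative weight vector (one per column).
#' @export
fit_nca <- function(x, y, lambda = 0.05, seed = 1L, max_iter = 200L,
                    tol = 1e-6) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  n <- nrow(x)
  xs <- standardize_columns(x)
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  objective_and_grad <- function(w) {
    z <- sweep(xs, 2, w, "*")
    sq <- rowSums(z^2)
    d <- outer(sq, sq, "+") - 2 * tcrossprod(z)
    d[d < 0] <- 0
    diag(d) <- Inf
    dmin <- apply(d, 1, min)
    dmin[!is.finite(dmin)] <- 0
    K <- exp(-(d - dmin))
    diag(K) <- 0
    P <- K / pmax(rowSums(K), .Machine$double.xmin)
    p_i <- rowSums(P * same)
    f <- mean(p_i) - lambda * sum(w^2)
    C <- p_i * P - P * same
    rc <- rowSums(C)
    cc <- colSums(C)
    x2 <- xs^2
    term <- as.numeric(crossprod(x2, rc + cc)) -
      2 * colSums(xs * (C %*% xs))
    g <- (2 * w / n) * term - 2 * lambda * w
    list(f = f, g = g)
  }

  with_seed(seed, {
    w <- rep(1, ncol(xs))
    og <- objective_and_grad(w)
    alpha <- 0.1
    for (it in seq_len(max_iter)) {
      accepted <- FALSE
      for (half in 1:30) {
        w_new <- w + alpha * og$g
        og_new <- objective_and_grad(w_new)
        if (is.finite(og_new$f) && og_new$f > og$f) {
          accepted <- TRUE
          break
        }
        alpha <- alpha / 2
      }
      if (!accepted) break
      converged <- abs(og_new$f - og$f) <= tol * (abs(og$f) + tol)
      w <- w_new
      og <- og_new
      alpha <- alpha * 1.2
      if (converged) break
    }
    w <- abs(w)
    names(w) <- colnames(x)
    w
  })
}

# Weighted 1-NN prediction used as the tuning loss.
predict_nca_1nn <- function(x_train, y_train, x_test, w) {
  zt <- sweep(x_train, 2, w, "*")
  zq <- sweep(x_test, 2, w, "*")
  d <- outer(rowSums(zq^2), rowSums(zt^2), "+") - 2 * tcrossprod(zq, zt)
  y_train[max.col(-d, ties.method = "first")]
}

#' Tune the NCA regularization parameter by stratified k-fold loss
#'
#' For every `lambda` on the grid, fits NCA on each training portion of a
#' stratified k-fold split and measures the misclassification rate of a
#' weighted 1-nearest-neighbor rule on the held-out fold; returns the
#' `lambda` minimizing the mean loss (ties broken toward the smallest
#' `lambda`).
#'
#' @param x Feature matrix.
#' @param y Class labels.
#' @param lambda_grid Candidate values; default 20 log-spaced values in
#'   `[1e-3, 1]`, spanning under- to over-regularized for the mean-scaled
#'   objective (at the top of the grid all weights collapse to zero).
#' @param folds Number of folds.
#' @param seed Seed controlling the fold assignment.
#' @param max_iter Ascent iterations per fit.
#' @return List with `best_lambda`, `lambda_grid`, `loss_per_lambda`.
#' @export
tune_nca_lambda <- function(x, y, lambda_grid = NULL, folds = 10L, seed = 1L,
                            max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  lambda_grid <- lambda_grid %||% exp(seq(log(1e-3), log(1), length.out = 20))
  if (!length(lambda_grid)) stop_config("lambda_grid", "must be nonempty")
  lambda_grid <- sort(lambda_grid)
  fold_sets <- kfold_split(y, k = folds, seed = seed, stratified = TRUE)
  for (f in fold_sets) {
    if (length(unique(y[-f])) < length(unique(y))) {
      stop("stratification error: a class is absent from a training fold",
           call. = FALSE)
    }
  }
  xs <- standardize_columns(x)
  losses <- matrix(NA_real_, nrow = length(fold_sets),
                   ncol = length(lambda_grid))
  for (fi in seq_along(fold_sets)) {
    test <- fold_sets[[fi]]
    for (li in seq_along(lambda_grid)) {
      w <- fit_nca(xs[-test, , drop = FALSE], y[-test], lambda_grid[li],
                   seed = derive_seed(seed, fi), max_iter = max_iter)
      pred <- predict_nca_1nn(xs[-test, , drop = FALSE], y[-test],
                              xs[test, , drop = FALSE], w)
      losses[fi, li] <- mean(pred != y[test])
    }
  }
  mean_loss <- colMeans(losses)
  best <- lambda_grid[which.min(mean_loss)]
  list(best_lambda = best, lambda_grid = lambda_grid,
       loss_per_lambda = mean_loss)
}

#' Threshold NCA weights and map selected columns to IMFs
#'
#' @param w Nonnegative weight vector (named, or supply `imf_map`).
#' @param tau Threshold tolerance; `T = tau * max(w)`.
#' @param imf_map Integer vector mapping each column to its IMF index;
#'   parsed from names of the form `i<j>_<stat>` when omitted.
#' @return List of class `nca_result` with `w`, `threshold`,
#'   `selected_columns` (indices), `selected_imfs` (integer set).
#' @export
nca_select <- function(w, tau = 0.02, imf_map = NULL) {
  if (!length(w) || any(w < 0)) {
    stop("`w` must be a nonempty nonnegative vector", call. = FALSE)
  }
  threshold <- tau * max(w)
  if (max(w) == 0) {
    warning("all NCA weights are zero; empty selection")
    selected <- integer(0)
  } else {
    selected <- which(w > threshold)
  }
  if (is.null(imf_map) && !is.null(names(w))) {
    imf_map <- suppressWarnings(as.integer(sub("^i(\\d+)_.*$", "\\1", names(w))))
  }
  selected_imfs <- if (is.null(imf_map)) integer(0) else {
    sort(unique(imf_map[selected]))
  }
  structure(list(w = w, tau = tau, threshold = threshold,
                 selected_columns = selected, selected_imfs = selected_imfs),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca_result> %d/%d columns above T = %.4g; IMFs selected: %s\n",
    length(x$selected_columns), length(x$w), x$threshold,
    paste(x$selected_imfs, collapse = ", ")))
  invisible(x)
}

#' Simulate a planted-informative feature table
#'
#' Benchmark design for selection methods: `n` samples, balanced binary
#' labels, `n_informative` columns whose class means differ by
#' `shift` standard deviations, and `n_noise` pure-noise columns. Column
#' names mark informative columns as IMFs 1..k and noise columns as higher
#' IMF indices so IMF-level recovery can be scored.
#'
#' @param n Number of rows.
#' @param n_informative,n_noise Column counts.
#' @param shift Class mean separation in standard deviations.
#' @param seed Seed.
#' @return List of class `feature_table` (`x`, `y`, `imf_of_column`,
#'   `informative` index vector).
#' @export
simulate_feature_table <- function(n = 500L, n_informative = 4L,
                                   n_noise = 16L, shift = 2, seed = 1L) {
  with_seed(seed, {
    p <- n_informative + n_noise
    y <- rep(c("A", "N"), length.out = n)
    x <- matrix(rnorm(n * p), n, p)
    x[y == "A", seq_len(n_informative)] <-
      x[y == "A", seq_len(n_informative)] + shift
    colnames(x) <- paste0("i", seq_len(p), "_stat")
    structure(list(x = x, y = y, imf_of_column = seq_len(p),
                   informative = seq_len(n_informative)),
              class = "feature_table")
  })
}
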