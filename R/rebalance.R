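#' Training-set class rebalancing: SMOTE, ROS, RUS
#'
#' Equalizes apnea/normal counts in a training fold. SMOTE synthesizes new
#' minority points on segments between existing minority points:
#' `x_syn = x_i + lambda * (xhat_i - x_i)` with `xhat_i` drawn uniformly from
#' the k nearest minority neighbors of `x_i` (Euclidean distance in feature
#' space) and `lambda ~ Uniform[0, 1]`. ROS replicates minority rows at
#' random; RUS deletes majority rows at random. Rebalancing belongs in
#' training folds only -- synthetic points in a test fold inflate
#' performance.
#'
#' @name rebalance
NULL

#' SMOTE minority oversampling
#'
#' Generates `x_maj_count - nrow(x_min)` synthetic rows. Base points are
#' cycled through the minority set uniformly; each draw (base index, chosen
#' neighbor, lambda) is logged in the `"draws"` attribute for audit.
#'
#' @param x_min Matrix of minority-class rows.
#' @param x_maj_count Majority class count to match.
#' @param k Number of nearest neighbors (`1 <= k < nrow(x_min)`).
#' @param seed Seed.
#' @param lambda Optional fixed interpolation factor (testing hook); default
#'   draws `Uniform[0, 1]` per synthetic point.
#' @return Matrix of synthetic rows (possibly 0 rows), with attribute
#'   `"draws"`: data.frame `(base, neighbor, lambda)` of logged draws.
#' @export
smote <- function(x_min, x_maj_count, k = 5L, seed = 1L, lambda = NULL) {
  x_min <- as.matrix(x_min)
  n_min <- nrow(x_min)
  if (k < 1L || k >= n_min) {
    stop(sprintf(
      "SMOTE needs 1 <= k < minority count (%d); use a smaller k than %d",
      n_min, k), call. = FALSE)
  }
  n_syn <- x_maj_count - n_min
  if (n_syn <= 0L) {
    out <- x_min[integer(0), , drop = FALSE]
    attr(out, "draws") <- data.frame(base = integer(0), neighbor = integer(0),
                                     lambda = numeric(0))
    return(out)
  }
  d <- as.matrix(dist(x_min))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  with_seed(seed, {
    base <- rep_len(seq_len(n_min), n_syn)
    chosen <- nn[cbind(base, sample.int(k, n_syn, replace = TRUE))]
    lam <- if (is.null(lambda)) runif(n_syn) else rep_len(lambda, n_syn)
    syn <- x_min[base, , drop = FALSE] +
      lam * (x_min[chosen, , drop = FALSE] - x_min[base, , drop = FALSE])
    attr(syn, "draws") <- data.frame(base = base, neighbor = chosen,
                                     lambda = lam)
    syn
  })
}

#' Random oversampling of the minority class
#'
#' @param x_min Matrix of minority rows.
#' @param x_maj_count Majority class count to match.
#' @param seed Seed.
#' @return Matrix of `x_maj_count - nrow(x_min)` replicated rows (each equal
#'   to some input row), with attribute `"indices"`.
#' @export
ros <- function(x_min, x_maj_count, seed = 1L) {
  x_min <- as.matrix(x_min)
  if (nrow(x_min) == 0L) stop("minority class is empty", call. = FALSE)
  n_rep <- x_maj_count - nrow(x_min)
  idx <- if (n_rep > 0L) {
    with_seed(seed, sample.int(nrow(x_min), n_rep, replace = TRUE))
  } else integer(0)
  out <- x_min[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Random undersampling of the majority class
#'
#' @param x_maj Matrix of majority rows.
#' @param x_min_count Minority class count to match.
#' @param seed Seed.
#' @return The retained majority rows (uniform sample without replacement of
#'   size `x_min_count`), with attribute `"indices"`.
#' @export
rus <- function(x_maj, x_min_count, seed = 1L) {
  x_maj <- as.matrix(x_maj)
  if (nrow(x_maj) < x_min_count) {
    stop("majority count is below the minority count", call. = FALSE)
  }
  idx <- if (nrow(x_maj) == x_min_count) seq_len(nrow(x_maj)) else {
    with_seed(seed, sort(sample.int(nrow(x_maj), x_min_count)))
  }
  out <- x_maj[idx, , drop = FALSE]
  attr(out, "indices") <- idx
  out
}

#' Rebalance a labeled training matrix
#'
#' @param x Feature matrix (rows = segments).
#' @param y Labels ("A"/"N" or 0/1, apnea positive).
#' @param method `"none"`, `"smote"`, `"ros"`, or `"rus"`.
#' @param k SMOTE neighbor count.
#' @param seed Seed.
#' @return List with balanced `x`, `y`, and the `draws`/`indices` log.
#' @export
rebalance_training <- function(x, y, method = c("none", "smote", "ros", "rus"),
                               k = 5L, seed = 1L) {
  method <- match.arg(method)
  yb <- as_apnea_indicator(y)
  if (method == "none") return(list(x = x, y = y, log = NULL))
  counts <- table(factor(yb, levels = c(0, 1)))
  min_cls <- if (counts[["1"]] <= counts[["0"]]) 1L else 0L
  maj_cls <- 1L - min_cls
  x_min <- x[yb == min_cls, , drop = FALSE]
  x_maj <- x[yb == maj_cls, , drop = FALSE]
  if (method == "smote") {
    k_eff <- min(k, nrow(x_min) - 1L)
    if (k_eff < k) {
      message(sprintf(
        "rebalance: minority count %d too small for k = %d; using k = %d",
        nrow(x_min), k, k_eff))
    }
    syn <- smote(x_min, nrow(x_maj), k = k_eff, seed = seed)
    list(x = rbind(x, syn),
         y = c(y, rep(if (min_cls == 1L) "A" else "N", nrow(syn))),
         log = attr(syn, "draws"))
  } else if (method == "ros") {
    rep_rows <- ros(x_min, nrow(x_maj), seed = seed)
    list(x = rbind(x, rep_rows),
         y = c(y, rep(if (min_cls == 1L) "A" else "N", nrow(rep_rows))),
         log = attr(rep_rows, "indices"))
  } else {
    kept <- rus(x_maj, nrow(x_min), seed = seed)
    keep_idx <- c(which(yb == min_cls), which(yb == maj_cls)[attr(kept, "indices")])
    keep_idx <- sort(keep_idx)
    list(x = x[keep_idx, , drop = FALSE], y = y[keep_idx],
         log = attr(kept, "indices"))
  }
}
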