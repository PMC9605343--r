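#' 1D deep convolutional network for ECG segment classification
#'
#' The classifier consumes one decomposition feature vector per 60-s segment
#' (6000 samples at 100 Hz) and emits apnea/normal probabilities. The
#' reference architecture is 8 feature-extraction blocks of
#' (conv 45 filters x kernel 32, 'same' padding, He-normal init; batch norm;
#' ReLU; max-pool 2/2; dropout 0.5) -- halving the temporal length
#' 6000 -> 3000 -> ... -> 46 -> 23 with floor division on odd lengths --
#' followed by flatten and 6 classification blocks of (dense 512, batch
#' norm, ReLU, dropout 0.5) and a final dense softmax over 2 classes.
#' Training minimizes cross-entropy with Adam. All randomness (weight init,
#' shuffling, dropout) is seeded, so runs are bit-reproducible on one
#' machine.
#'
#' Internally, convolutional activations are held channels-first
#' (`C x (L*B)`) so batch normalization and the activation nonlinearities are
#' plain vectorized arithmetic; the convolutions run in compiled code as one
#' BLAS call per kernel tap.
#'
#' @name cnn_model
NULL

#' Architecture specification
#'
#' @param input_len Segment length in samples.
#' @param n_blocks Feature-extraction blocks.
#' @param filters Convolution channels per block.
#' @param kernel_size Convolution kernel length.
#' @param fc_blocks Fully-connected classification blocks.
#' @param fc_units Units per dense block.
#' @param dropout Dropout rate in every block.
#' @param n_classes Output classes.
#' @return List of class `cnn_spec` with the pooled `block_lengths` chain.
#' @export
cnn_spec <- function(input_len = 6000L, n_blocks = 8L, filters = 45L,
                     kernel_size = 32L, fc_blocks = 6L, fc_units = 512L,
                     dropout = 0.5, n_classes = 2L) {
  check_number(input_len, "input_len", lower = 2)
  check_number(n_blocks, "n_blocks", lower = 1)
  check_number(filters, "filters", lower = 1)
  check_number(kernel_size, "kernel_size", lower = 1)
  check_number(fc_blocks, "fc_blocks", lower = 0)
  check_number(fc_units, "fc_units", lower = 1)
  check_number(dropout, "dropout", lower = 0, upper = 1 - 1e-9)
  check_number(n_classes, "n_classes", lower = 2)
  lens <- integer(n_blocks)
  L <- as.integer(input_len)
  for (i in seq_len(n_blocks)) {
    L <- L %/% 2L
    if (L < 2L) {
      stop_config("input_len", sprintf(
        "too short: pooled length drops below 2 at block %d", i))
    }
    lens[i] <- L
  }
  structure(list(input_len = as.integer(input_len),
                 n_blocks = as.integer(n_blocks),
                 filters = as.integer(filters),
                 kernel_size = as.integer(kernel_size),
                 fc_blocks = as.integer(fc_blocks),
                 fc_units = as.integer(fc_units),
                 dropout = dropout, n_classes = as.integer(n_classes),
                 block_lengths = lens),
            class = "cnn_spec")
}

new_bn <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

#' Build (initialize) a CNN model
#'
#' Weights are He-normal initialized (`sd = sqrt(2 / fan_in)`), biases zero.
#'
#' @param spec A [cnn_spec()].
#' @param seed Seed for the weight draw.
#' @return List of class `cnn_model`.
#' @export
cnn_build <- function(spec = cnn_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  with_seed(seed, {
    conv <- vector("list", spec$n_blocks)
    cin <- 1L
    for (i in seq_len(spec$n_blocks)) {
      fan_in <- spec$kernel_size * cin
      conv[[i]] <- list(
        W = array(rnorm(spec$filters * cin * spec$kernel_size,
                        sd = sqrt(2 / fan_in)),
                  dim = c(spec$filters, cin, spec$kernel_size)),
        b = rep(0, spec$filters),
        bn = new_bn(spec$filters))
      cin <- spec$filters
    }
    flat_dim <- tail(spec$block_lengths, 1L) * spec$filters
    fc <- vector("list", spec$fc_blocks)
    fin <- flat_dim
    for (i in seq_len(spec$fc_blocks)) {
      fc[[i]] <- list(
        W = matrix(rnorm(fin * spec$fc_units, sd = sqrt(2 / fin)),
                   fin, spec$fc_units),
        b = rep(0, spec$fc_units),
        bn = new_bn(spec$fc_units))
      fin <- spec$fc_units
    }
    out <- list(W = matrix(rnorm(fin * spec$n_classes, sd = sqrt(2 / fin)),
                           fin, spec$n_classes),
                b = rep(0, spec$n_classes))
    structure(list(spec = spec, conv = conv, fc = fc, out = out,
                   seed = as.integer(seed), history = NULL),
              class = "cnn_model")
  })
}

#' Number of trainable parameters
#'
#' Counts convolution and dense weights/biases plus the batch-norm
#' scale/shift pairs (running statistics are not trainable).
#'
#' @param model A `cnn_model`.
#' @return Named integer vector per layer plus a `"total"` entry.
#' @export
cnn_count_params <- function(model) {
  cnt <- c()
  for (i in seq_along(model$conv)) {
    blk <- model$conv[[i]]
    cnt[paste0("conv", i)] <- length(blk$W) + length(blk$b)
    cnt[paste0("conv", i, "_bn")] <- length(blk$bn$gamma) + length(blk$bn$beta)
  }
  for (i in seq_along(model$fc)) {
    blk <- model$fc[[i]]
    cnt[paste0("fc", i)] <- length(blk$W) + length(blk$b)
    cnt[paste0("fc", i, "_bn")] <- length(blk$bn$gamma) + length(blk$bn$beta)
  }
  cnt["out"] <- length(model$out$W) + length(model$out$b)
  c(cnt, total = sum(cnt))
}

# Batch norm over a channels-first matrix (C x N): statistics per row,
# applied by vector recycling down columns. Used for the conv blocks.
bn_rows_forward <- function(bn, z, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(z)
    v <- rowMeans(z * z) - mu^2
    v[v < 0] <- 0
    inv <- 1 / sqrt(v + eps)
    zh <- (z - mu) * inv
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v
  } else {
    inv <- 1 / sqrt(bn$run_var + eps)
    zh <- (z - bn$run_mean) * inv
  }
  list(y = zh * bn$gamma + bn$beta, zh = zh, inv = inv, bn = bn)
}

bn_rows_backward <- function(bn, cache, dy) {
  dgamma <- rowSums(dy * cache$zh)
  dbeta <- rowSums(dy)
  gi <- bn$gamma * cache$inv
  m1 <- rowMeans(dy)
  m2 <- rowMeans(dy * cache$zh)
  dz <- gi * (dy - m1 - cache$zh * m2)
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# Batch norm over a samples-first matrix (B x U): statistics per column.
# Used for the (small) dense blocks.
bn_cols_forward <- function(bn, z, training, momentum = 0.1, eps = 1e-5) {
  out <- bn_rows_forward(bn, t(z), training, momentum, eps)
  list(y = t(out$y), zh = t(out$zh), inv = out$inv, bn = out$bn)
}

bn_cols_backward <- function(bn, cache, dy) {
  out <- bn_rows_backward(bn, list(zh = t(cache$zh), inv = cache$inv), t(dy))
  list(dz = t(out$dz), dgamma = out$dgamma, dbeta = out$dbeta)
}

pool_indices <- function(L, B) {
  L2 <- L %/% 2L
  base <- rep((seq_len(B) - 1L) * L, each = L2)
  o1 <- base + rep(seq(1L, by = 2L, length.out = L2), times = B)
  list(L2 = L2, o1 = o1, o2 = o1 + 1L)
}

# Flatten channels-first conv activations (C x (L*B)) to B x (L*C) rows.
flatten_act <- function(a, L, B, C) {
  t(matrix(aperm(array(a, c(C, L, B)), c(2L, 1L, 3L)), nrow = L * C))
}

unflatten_grad <- function(df, L, B, C) {
  matrix(aperm(array(t(df), c(L, C, B)), c(2L, 1L, 3L)), nrow = C,
         ncol = L * B)
}

# Full forward pass. `training` enables batch statistics and dropout (which
# consumes the current RNG stream). Returns probabilities and, when
# `keep_cache`, everything backward needs. `dropout` can be switched off
# independently of `training` for batch-norm re-estimation passes, and
# `bn_momentum` overrides the running-statistics update rate there.
cnn_forward <- function(model, X, training = FALSE, keep_cache = FALSE,
                        dropout = TRUE, bn_momentum = 0.1) {
  spec <- model$spec
  B <- nrow(X)
  if (ncol(X) != spec$input_len) {
    stop(sprintf("input length %d does not match the expected %d samples",
                 ncol(X), spec$input_len), call. = FALSE)
  }
  use_dropout <- training && dropout && spec$dropout > 0
  keep <- 1 - spec$dropout
  a <- matrix(as.vector(t(X)), nrow = 1L)
  L <- spec$input_len
  cache <- list(conv = vector("list", spec$n_blocks),
                fc = vector("list", spec$fc_blocks))
  for (i in seq_len(spec$n_blocks)) {
    blk <- model$conv[[i]]
    z <- conv1d_fwd_cpp(a, blk$W, blk$b, L, B)
    bnf <- bn_rows_forward(blk$bn, z, training, momentum = bn_momentum)
    if (training) model$conv[[i]]$bn <- bnf$bn
    relu_mask <- bnf$y > 0
    r <- bnf$y * relu_mask
    pi <- pool_indices(L, B)
    a1 <- r[, pi$o1, drop = FALSE]
    a2 <- r[, pi$o2, drop = FALSE]
    pmask <- a1 >= a2
    p <- a1 * pmask + a2 * !pmask
    if (use_dropout) {
      dmask <- (matrix(runif(length(p)), nrow(p)) < keep) / keep
      p <- p * dmask
    } else {
      dmask <- NULL
    }
    if (keep_cache) {
      cache$conv[[i]] <- list(input = a, L_in = L, bn = bnf,
                              relu_mask = relu_mask, pool = pi,
                              pmask = pmask, dmask = dmask)
    }
    a <- p
    L <- pi$L2
  }
  C <- spec$filters
  f <- flatten_act(a, L, B, C)
  cache$flat <- list(L = L, C = C)
  for (i in seq_len(spec$fc_blocks)) {
    blk <- model$fc[[i]]
    z <- f %*% blk$W
    z <- z + rep(blk$b, each = B)
    bnf <- bn_cols_forward(blk$bn, z, training, momentum = bn_momentum)
    if (training) model$fc[[i]]$bn <- bnf$bn
    relu_mask <- bnf$y > 0
    r <- bnf$y * relu_mask
    if (use_dropout) {
      dmask <- (matrix(runif(length(r)), nrow(r)) < keep) / keep
      r <- r * dmask
    } else {
      dmask <- NULL
    }
    if (keep_cache) {
      cache$fc[[i]] <- list(input = f, bn = bnf, relu_mask = relu_mask,
                            dmask = dmask)
    }
    f <- r
  }
  logits <- f %*% model$out$W
  logits <- logits + rep(model$out$b, each = B)
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits)
  p <- p / rowSums(p)
  cache$out_input <- if (keep_cache) f else NULL
  list(probs = p, cache = if (keep_cache) cache else NULL, model = model)
}

# Backward pass from softmax gradient dlogits (B x n_classes).
cnn_backward <- function(model, cache, dlogits) {
  spec <- model$spec
  B <- nrow(dlogits)
  grads <- list(conv = vector("list", spec$n_blocks),
                fc = vector("list", spec$fc_blocks))
  grads$out <- list(W = crossprod(cache$out_input, dlogits),
                    b = colSums(dlogits))
  df <- tcrossprod(dlogits, model$out$W)
  for (i in rev(seq_len(spec$fc_blocks))) {
    cc <- cache$fc[[i]]
    if (!is.null(cc$dmask)) df <- df * cc$dmask
    df <- df * cc$relu_mask
    bnb <- bn_cols_backward(model$fc[[i]]$bn, cc$bn, df)
    dz <- bnb$dz
    grads$fc[[i]] <- list(W = crossprod(cc$input, dz), b = colSums(dz),
                          gamma = bnb$dgamma, beta = bnb$dbeta)
    df <- tcrossprod(dz, model$fc[[i]]$W)
  }
  L <- cache$flat$L
  da <- unflatten_grad(df, L, B, cache$flat$C)
  for (i in rev(seq_len(spec$n_blocks))) {
    cc <- cache$conv[[i]]
    if (!is.null(cc$dmask)) da <- da * cc$dmask
    dr <- matrix(0, nrow(da), cc$L_in * B)
    dr[, cc$pool$o1] <- da * cc$pmask
    dr[, cc$pool$o2] <- da * (!cc$pmask)
    dr <- dr * cc$relu_mask
    bnb <- bn_rows_backward(model$conv[[i]]$bn, cc$bn, dr)
    cv <- conv1d_bwd_cpp(cc$input, model$conv[[i]]$W, bnb$dz, cc$L_in, B)
    grads$conv[[i]] <- list(W = cv$dw, b = as.numeric(cv$db),
                            gamma = bnb$dgamma, beta = bnb$dbeta)
    da <- cv$dx
  }
  grads
}

#' Training configuration
#'
#' The reference study leaves epochs, batch size and learning rate
#' unspecified; these defaults are declared here and logged with every run.
#'
#' @param epochs Training epochs (>= 1).
#' @param batch_size Mini-batch size (>= 2; batch norm needs batch
#'   statistics).
#' @param learning_rate Adam step size.
#' @param seed Seed controlling shuffling and dropout.
#' @return List of class `cnn_train_config`.
#' @export
cnn_train_config <- function(epochs = 70L, batch_size = 128L,
                             learning_rate = 1e-3, seed = 1L) {
  check_number(epochs, "epochs", lower = 1)
  check_number(batch_size, "batch_size", lower = 2)
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_train_config")
}

adam_step <- function(param, grad, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * grad
  v <- beta2 * v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train the CNN with Adam on cross-entropy
#'
#' @param model A `cnn_model` from [cnn_build()].
#' @param X Segment matrix (rows = segments, `input_len` columns).
#' @param y Labels ("A"/"N" or 0/1, apnea positive); both classes must be
#'   present.
#' @param config A [cnn_train_config()].
#' @return The trained model; `model$history` holds per-epoch mean loss and
#'   training accuracy.
#' @export
cnn_train <- function(model, X, y, config = cnn_train_config()) {
  stopifnot(inherits(model, "cnn_model"))
  if (!inherits(config, "cnn_train_config")) {
    stop("`config` must be a `cnn_train_config`", call. = FALSE)
  }
  yb <- as_apnea_indicator(y)
  n <- nrow(X)
  if (n == 0L || length(yb) != n) {
    stop("`X` and `y` must be nonempty and matched", call. = FALSE)
  }
  if (length(unique(yb)) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  lr <- config$learning_rate
  state <- NULL
  tstep <- 0L
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0))
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      ep_correct <- 0
      ep_n <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch norm needs >= 2 samples
        xb <- X[idx, , drop = FALSE]
        yb_b <- yb[idx]
        fw <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE)
        model <- fw$model
        p <- fw$probs
        loss <- -mean(log(pmax(p[cbind(seq_along(yb_b), yb_b + 1L)], 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf(
            "training diverged: non-finite loss at epoch %d (lr=%g); lower the learning rate",
            ep, lr), call. = FALSE)
        }
        onehot <- matrix(0, length(yb_b), model$spec$n_classes)
        onehot[cbind(seq_along(yb_b), yb_b + 1L)] <- 1
        dlogits <- (p - onehot) / length(yb_b)
        grads <- cnn_backward(model, fw$cache, dlogits)
        if (is.null(state)) {
          state <- list(m = adam_init_from(grads), v = adam_init_from(grads))
        }
        tstep <- tstep + 1L
        upd <- apply_adam(model, grads, state, lr, tstep)
        model <- upd$model
        state <- upd$state
        ep_loss <- ep_loss + loss * length(idx)
        ep_correct <- ep_correct + sum((p[, 2L] >= 0.5) == (yb_b == 1L))
        ep_n <- ep_n + length(idx)
      }
      history <- rbind(history, data.frame(
        epoch = ep, loss = ep_loss / ep_n, accuracy = ep_correct / ep_n))
    }
    # Re-estimate batch-norm running statistics with dropout off: statistics
    # collected under active dropout carry its variance inflation through
    # the layer stack and bias inference. Cumulative-average momentum (1/t)
    # makes the running values the exact mean over these clean batches.
    upd <- 0L
    for (pass in 1:2) {
      ord <- sample(n)
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next
        upd <- upd + 1L
        fw <- cnn_forward(model, X[idx, , drop = FALSE], training = TRUE,
                          dropout = FALSE, bn_momentum = 1 / upd)
        model <- fw$model
      }
    }
  })
  model$history <- history
  model
}

adam_init_from <- function(grads) {
  rapply(grads, function(x) x * 0, how = "replace")
}

# Walk the grads structure and update every matching model parameter.
apply_adam <- function(model, grads, state, lr, t) {
  upd_leaf <- function(param, grad, m, v) {
    a <- adam_step(param, grad, m, v, lr, t)
    list(p = a$param, m = a$m, v = a$v)
  }
  for (i in seq_along(grads$conv)) {
    for (nm in c("W", "b")) {
      a <- upd_leaf(model$conv[[i]][[nm]], grads$conv[[i]][[nm]],
                    state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      model$conv[[i]][[nm]] <- a$p
      state$m$conv[[i]][[nm]] <- a$m
      state$v$conv[[i]][[nm]] <- a$v
    }
    for (nm in c("gamma", "beta")) {
      a <- upd_leaf(model$conv[[i]]$bn[[nm]], grads$conv[[i]][[nm]],
                    state$m$conv[[i]][[nm]], state$v$conv[[i]][[nm]])
      model$conv[[i]]$bn[[nm]] <- a$p
      state$m$conv[[i]][[nm]] <- a$m
      state$v$conv[[i]][[nm]] <- a$v
    }
  }
  for (i in seq_along(grads$fc)) {
    for (nm in c("W", "b")) {
      a <- upd_leaf(model$fc[[i]][[nm]], grads$fc[[i]][[nm]],
                    state$m$fc[[i]][[nm]], state$v$fc[[i]][[nm]])
      model$fc[[i]][[nm]] <- a$p
      state$m$fc[[i]][[nm]] <- a$m
      state$v$fc[[i]][[nm]] <- a$v
    }
    for (nm in c("gamma", "beta")) {
      a <- upd_leaf(model$fc[[i]]$bn[[nm]], grads$fc[[i]][[nm]],
                    state$m$fc[[i]][[nm]], state$v$fc[[i]][[nm]])
      model$fc[[i]]$bn[[nm]] <- a$p
      state$m$fc[[i]][[nm]] <- a$m
      state$v$fc[[i]][[nm]] <- a$v
    }
  }
  a <- upd_leaf(model$out$W, grads$out$W, state$m$out$W, state$v$out$W)
  model$out$W <- a$p; state$m$out$W <- a$m; state$v$out$W <- a$v
  a <- upd_leaf(model$out$b, grads$out$b, state$m$out$b, state$v$out$b)
  model$out$b <- a$p; state$m$out$b <- a$m; state$v$out$b <- a$v
  list(model = model, state = state)
}

#' Predict class probabilities
#'
#' Runs the network in inference mode (batch-norm running statistics, no
#' dropout), so outputs are deterministic and independent of batch
#' composition.
#'
#' @param model A `cnn_model`.
#' @param X Segment matrix.
#' @param batch_size Chunk size for memory control.
#' @return Matrix with columns `normal` and `apnea`; rows sum to 1. The
#'   apnea probability is always the second column.
#' @export
cnn_predict_proba <- function(model, X, batch_size = 256L) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, model$spec$n_classes)
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    out[idx, ] <- cnn_forward(model, X[idx, , drop = FALSE],
                              training = FALSE)$probs
  }
  colnames(out) <- c("normal", "apnea")[seq_len(min(2L, ncol(out)))]
  out
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model> %d conv blocks (%d filters, kernel %d) -> lengths %s; %d fc blocks x %d; %s\n",
    x$spec$n_blocks, x$spec$filters, x$spec$kernel_size,
    paste(x$spec$block_lengths, collapse = "-"), x$spec$fc_blocks,
    x$spec$fc_units,
    if (is.null(x$history)) "untrained" else
      sprintf("trained %d epochs (final loss %.4f)",
              nrow(x$history), tail(x$history$loss, 1))))
  invisible(x)
}
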