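# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library calls never perturb user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream index; keeps every
# subject / fold / stage on an independent, reproducible stream.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807 + 11) %%
    2147483647)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(field, "must be a single finite number")
  }
  if (x < lower) stop_config(field, sprintf("must be >= %s", lower))
  if (x > upper) stop_config(field, sprintf("must be <= %s", upper))
  invisible(x)
}

# Simple peak detector: local maxima above `min_height`, at least
# `min_distance` samples apart (greedy, highest first). Used by the synthetic
# generator's audits, not by the classification pipeline.
find_peaks <- function(x, min_height = -Inf, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (min_distance <= 1L || length(cand) < 2L) return(cand)
  cand <- cand[order(x[cand], decreasing = TRUE)]
  keep <- logical(0)
  taken <- integer(0)
  for (p in cand) {
    if (!length(taken) || all(abs(taken - p) >= min_distance)) {
      taken <- c(taken, p)
    }
  }
  sort(taken)
}
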