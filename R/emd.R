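#' Empirical mode decomposition by sifting
#'
#' EMD adaptively decomposes a non-stationary signal `y` into a small number
#' of intrinsic mode functions (IMFs) plus a residue, `y = sum_j i_j + r_n`.
#' Each IMF is extracted by sifting: the mean of the cubic-spline upper and
#' lower extrema envelopes is repeatedly subtracted until the component
#' satisfies the two IMF requirements (extrema and zero-crossing counts equal
#' or differing by one; locally zero-mean envelope).
#'
#' @name emd
NULL

#' Sifting configuration
#'
#' @param sd_tol Cauchy stopping tolerance on the normalized squared change
#'   between successive sift iterates (classic value 0.2).
#' @param mean_tol Envelope-mean requirement: sifting may stop once
#'   `max|m| <= mean_tol * max|h|`.
#' @param max_sift Maximum sift iterations per IMF.
#' @return List of class `sift_config`.
#' @export
sift_config <- function(sd_tol = 0.2, mean_tol = 0.05, max_sift = 100L) {
  check_number(sd_tol, "sd_tol", lower = 0)
  check_number(mean_tol, "mean_tol", lower = 0)
  check_number(max_sift, "max_sift", lower = 1)
  structure(list(sd_tol = sd_tol, mean_tol = mean_tol,
                 max_sift = as.integer(max_sift)), class = "sift_config")
}

# Local extrema with plateau collapse: a flat run bordered by a rise and a
# fall (or vice versa) counts as one extremum at its midpoint.
find_extrema <- function(y) {
  n <- length(y)
  if (n < 3L) return(list(maxima = integer(0), minima = integer(0)))
  s <- sign(diff(y))
  nz <- which(s != 0)
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  sv <- s[nz]
  chg <- which(sv[-length(sv)] != sv[-1L])
  if (!length(chg)) return(list(maxima = integer(0), minima = integer(0)))
  pos <- as.integer((nz[chg] + 1L + nz[chg + 1L]) %/% 2L)
  is_max <- sv[chg] > 0
  list(maxima = pos[is_max], minima = pos[!is_max])
}

# Count zero crossings: sign changes between consecutive nonzero samples;
# a run of exact zeros separating opposite signs counts once.
count_zero_crossings <- function(y) {
  s <- sign(y)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0L)
}

imf_criterion_counts <- function(y) {
  ex <- find_extrema(y)
  n_ext <- length(ex$maxima) + length(ex$minima)
  c(extrema = n_ext, crossings = count_zero_crossings(y))
}

#' Check the extrema / zero-crossing IMF requirement
#'
#' @param y Numeric vector.
#' @return `TRUE` when `|#extrema - #zero-crossings| <= 1`.
#' @export
imf_valid <- function(y) {
  cts <- imf_criterion_counts(y)
  abs(cts[["extrema"]] - cts[["crossings"]]) <= 1L
}

#' Mean of the cubic-spline extrema envelopes
#'
#' Fits natural cubic splines through the local maxima and local minima
#' (with the two extrema nearest each boundary mirrored outside the signal to
#' suppress spline end swings) and returns the average of the two envelopes.
#'
#' @param y Numeric vector with at least one maximum, one minimum, and three
#'   extrema in total.
#' @return The envelope mean, or `NULL` (monotone sentinel) when `y` has too
#'   few extrema to support envelopes -- the sifter interprets that as a
#'   residue, it is not an error.
#' @export
envelope_mean <- function(y) {
  n <- length(y)
  ex <- find_extrema(y)
  if (length(ex$maxima) < 1L || length(ex$minima) < 1L ||
      (length(ex$maxima) + length(ex$minima)) < 3L) return(NULL)
  upper <- spline_envelope(ex$maxima, y[ex$maxima], n)
  lower <- spline_envelope(ex$minima, y[ex$minima], n)
  (upper + lower) / 2
}

# Natural cubic spline through (pos, val), evaluated at 1..n, after mirroring
# the first/last two knots about the signal ends.
spline_envelope <- function(pos, val, n) {
  k <- length(pos)
  m_head <- seq_len(min(2L, k))
  m_tail <- seq.int(max(1L, k - 1L), k)
  px <- c(2 - rev(pos[m_head]), pos, 2 * n - rev(pos[m_tail]))
  py <- c(rev(val[m_head]), val, rev(val[m_tail]))
  keep <- !duplicated(px)
  f <- splinefun(px[keep], py[keep], method = "natural")
  f(seq_len(n))
}

#' Extract one intrinsic mode function by sifting
#'
#' Iterates `h <- h - envelope_mean(h)` until the extrema/zero-crossing
#' requirement holds and either the envelope-mean requirement
#' (`max|m| <= mean_tol * max|h|`) or the Cauchy criterion
#' (`sum(m^2)/sum(h^2) < sd_tol`) is met, or `max_sift` is reached.
#'
#' @param y Numeric vector (non-monotone).
#' @param stop A [sift_config()].
#' @return List with `imf`, `iterations`, and logical `converged`
#'   (`FALSE` when `max_sift` was exhausted) and `monotone` (`TRUE` when the
#'   input had too few extrema to sift at all).
#' @export
sift <- function(y, stop = sift_config()) {
  h <- y
  for (it in seq_len(stop$max_sift)) {
    m <- envelope_mean(h)
    if (is.null(m)) {
      return(list(imf = h, iterations = it, converged = TRUE, monotone = TRUE))
    }
    cts <- imf_criterion_counts(h)
    req1 <- abs(cts[["extrema"]] - cts[["crossings"]]) <= 1L
    req2 <- max(abs(m)) <= stop$mean_tol * max(abs(h))
    if (req1 && req2) {
      return(list(imf = h, iterations = it, converged = TRUE, monotone = FALSE))
    }
    h_new <- h - m
    sd_crit <- sum(m^2) / sum(h^2)
    if (sd_crit < stop$sd_tol) {
      cts_new <- imf_criterion_counts(h_new)
      if (abs(cts_new[["extrema"]] - cts_new[["crossings"]]) <= 1L) {
        return(list(imf = h_new, iterations = it, converged = TRUE,
                    monotone = FALSE))
      }
    }
    h <- h_new
  }
  # max_sift exhausted: return the current iterate with converged = FALSE
  # (recorded per-IMF in the imf_set; deliberately a flag, not a condition)
  list(imf = h, iterations = stop$max_sift, converged = FALSE, monotone = FALSE)
}

#' Decompose a signal into intrinsic mode functions
#'
#' Repeatedly sifts out IMFs until the residue is monotone (or has at most
#' two extrema) or `max_imfs` is reached. The residue is obtained by exact
#' telescoping subtraction, so `y == Reduce(`+`, imfs) + residue` to machine
#' precision.
#'
#' @param y Numeric vector, length >= 16.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param stop A [sift_config()].
#' @return An `imf_set`: list with `imfs` (list of numeric vectors),
#'   `residue`, `sift_counts`, and `converged` flags per IMF.
#' @export
emd_decompose <- function(y, max_imfs = 6L, stop = sift_config()) {
  if (!is.numeric(y) || length(y) < 16L) {
    stop("`y` must be a numeric vector of length >= 16", call. = FALSE)
  }
  check_number(max_imfs, "max_imfs", lower = 1)
  r <- as.numeric(y)
  imfs <- list()
  counts <- integer(0)
  conv <- logical(0)
  while (length(imfs) < max_imfs) {
    ex <- find_extrema(r)
    if (length(ex$maxima) < 1L || length(ex$minima) < 1L ||
        (length(ex$maxima) + length(ex$minima)) <= 2L) {
      break
    }
    s <- sift(r, stop)
    if (s$monotone) break
    imfs[[length(imfs) + 1L]] <- s$imf
    counts <- c(counts, s$iterations)
    conv <- c(conv, s$converged)
    r <- r - s$imf
  }
  structure(list(imfs = imfs, residue = r, sift_counts = counts,
                 converged = conv, n = length(y)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMFs + residue (length %d); sift counts: %s\n",
    length(x$imfs), x$n, paste(x$sift_counts, collapse = ", ")))
  invisible(x)
}

#' Build IMF combination features
#'
#' The screening pipeline feeds the classifier one of four decomposition
#' features per segment: `IMF1 = i1`, `IMF2 = i2`, `IMF12 = i1 + i2`,
#' `IMF123 = i1 + i2 + i3`.
#'
#' @param imfset An `imf_set` from [emd_decompose()].
#' @param kinds Character subset of `c("IMF1","IMF2","IMF12","IMF123")`.
#' @param segment_id Optional identifier used in error messages.
#' @return Named list of numeric vectors, one per requested kind.
#' @export
build_imf_features <- function(imfset,
                               kinds = c("IMF1", "IMF2", "IMF12", "IMF123"),
                               segment_id = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  need <- c(IMF1 = 1L, IMF2 = 2L, IMF12 = 2L, IMF123 = 3L)
  out <- list()
  for (k in kinds) {
    if (length(imfset$imfs) < need[[k]]) {
      stop(sprintf("feature %s unavailable%s: decomposition produced %d IMF(s), needs %d",
        k, if (is.null(segment_id)) "" else paste0(" for segment ", segment_id),
        length(imfset$imfs), need[[k]]), call. = FALSE)
    }
    out[[k]] <- switch(k,
      IMF1 = imfset$imfs[[1L]],
      IMF2 = imfset$imfs[[2L]],
      IMF12 = imfset$imfs[[1L]] + imfset$imfs[[2L]],
      IMF123 = imfset$imfs[[1L]] + imfset$imfs[[2L]] + imfset$imfs[[3L]])
  }
  out
}
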