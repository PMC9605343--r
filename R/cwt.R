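#' Complex Morlet continuous wavelet transform
#'
#' The scalogram representation used to visualize decomposed ECG segments:
#' each analysis row is the convolution of the signal with a complex Morlet
#' wavelet -- a complex oscillation at frequency `f0` under a Gaussian
#' envelope of temporal standard deviation `sigma_t(f0) = nc / (2*pi*f0)`,
#' where `nc` is the number of cycles inside the Gaussian bell. The envelope
#' is scaled by `A(sigma_t) = 1 / sqrt(sigma_t * sqrt(pi))` so its continuous
#' L2 energy equals one.
#'
#' @name cwt_spectro
NULL

#' Morlet analysis parameters
#'
#' @param freqs Strictly increasing analysis frequencies (Hz), each below
#'   the Nyquist frequency of the signal they are applied to. Default: 64
#'   log-spaced frequencies over 0.1--10 Hz.
#' @param nc Cycles under the Gaussian bell (dimensionless, > 0).
#' @param support Envelope half-width at which the wavelet is truncated, in
#'   units of `sigma_t`.
#' @return List of class `morlet_params`.
#' @export
morlet_params <- function(freqs = exp(seq(log(0.1), log(10), length.out = 64)),
                          nc = 6, support = 6) {
  check_number(nc, "nc", lower = 1e-9)
  check_number(support, "support", lower = 1e-9)
  if (!is.numeric(freqs) || !length(freqs) || any(diff(freqs) <= 0) ||
      any(freqs <= 0)) {
    stop_config("freqs", "must be positive and strictly increasing")
  }
  structure(list(freqs = as.numeric(freqs), nc = nc, support = support),
            class = "morlet_params")
}

#' Sampled complex Morlet mother wavelet
#'
#' @param f0 Center frequency, Hz (must be below `fs/2`).
#' @param nc Cycles under the Gaussian bell.
#' @param fs Sampling rate, samples/s.
#' @param support Truncation half-width in units of `sigma_t`.
#' @return Complex vector sampled at `1/fs` spacing on
#'   `[-support*sigma_t, +support*sigma_t]` (odd length, centered).
#' @export
morlet_wavelet <- function(f0, nc = 6, fs = 100, support = 6) {
  check_number(f0, "f0", lower = 1e-12)
  if (f0 >= fs / 2) {
    stop_config("f0", sprintf("must be below the Nyquist frequency %g", fs / 2))
  }
  sigma <- nc / (2 * pi * f0)
  k <- ceiling(support * sigma * fs)
  t <- (-k:k) / fs
  amp <- 1 / sqrt(sigma * sqrt(pi))
  amp * exp(-t^2 / (2 * sigma^2)) * exp(2i * pi * f0 * t)
}

#' Continuous wavelet transform of a real signal
#'
#' Row `f` of the result is the "same"-length, zero-padded convolution of
#' `x` with the Morlet wavelet at frequency `freqs[f]`. The default FFT
#' route is algebraically identical to direct time-domain convolution
#' (`method = "direct"`), which serves as the slow reference implementation.
#'
#' @param x Real numeric vector, longer than the longest wavelet support.
#' @param params A [morlet_params()].
#' @param fs Sampling rate, samples/s.
#' @param method `"fft"` (fast) or `"direct"` (reference).
#' @return A `scalogram`: list with complex matrix `x`
#'   (`n_freqs x n_samples`), `freqs`, `fs`.
#' @export
cwt_morlet <- function(x, params = morlet_params(), fs = 100,
                       method = c("fft", "direct")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  wavelets <- lapply(params$freqs, morlet_wavelet, nc = params$nc, fs = fs,
                     support = params$support)
  longest <- max(vapply(wavelets, length, integer(1)))
  if (n <= longest) {
    stop(sprintf(paste0(
      "signal (length %d) is shorter than the longest wavelet support (%d);",
      " raise the minimum analysis frequency"), n, longest), call. = FALSE)
  }
  X <- matrix(0i, nrow = length(params$freqs), ncol = n)
  for (j in seq_along(wavelets)) {
    X[j, ] <- if (method == "fft") {
      conv_same_fft(x, wavelets[[j]])
    } else {
      conv_same_direct(x, wavelets[[j]])
    }
  }
  structure(list(x = X, freqs = params$freqs, fs = fs), class = "scalogram")
}

# "Same"-length zero-padded convolution with an odd-length centered kernel,
# via FFT of the next power-of-two length.
conv_same_fft <- function(x, w) {
  n <- length(x)
  m <- length(w)
  k <- (m - 1L) %/% 2L
  nfft <- stats::nextn(n + m - 1L, 2)
  y <- fft(fft(c(x, rep(0, nfft - n))) * fft(c(w, rep(0+0i, nfft - m))),
           inverse = TRUE) / nfft
  y[(k + 1L):(k + n)]
}

# Direct time-domain convolution ("same", zero padding): accumulates
# w[j] * x shifted, one kernel tap at a time. Reference oracle for the FFT
# route.
conv_same_direct <- function(x, w) {
  n <- length(x)
  m <- length(w)
  k <- (m - 1L) %/% 2L
  y <- complex(n)
  # y[t] = sum_j w[j] * x[t + k + 1 - j], zero outside 1..n
  for (j in seq_len(m)) {
    lo <- max(1L, j - k)
    hi <- min(n, n + j - k - 1L)
    if (lo > hi) next
    y[lo:hi] <- y[lo:hi] + w[j] * x[(lo - j + k + 1L):(hi - j + k + 1L)]
  }
  y
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d frequencies (%.3g-%.3g Hz) x %d samples at %g Hz\n",
    length(x$freqs), min(x$freqs), max(x$freqs), ncol(x$x), x$fs))
  invisible(x)
}

#' Render a scalogram to a square image matrix
#'
#' Takes the (log-)magnitude, resamples it to `out_size x out_size` by
#' bilinear interpolation, and min-max scales to `[0, 1]`. Row 1 of the
#' returned matrix is the highest analysis frequency (frequency ascending
#' bottom-to-top in image convention). A degenerate all-equal magnitude maps
#' to an all-zero image.
#'
#' @param s A `scalogram`.
#' @param out_size Output side length in pixels.
#' @param value_map `"abs"` or `"log-abs"` (`log1p` of the magnitude).
#' @return `out_size x out_size` numeric matrix in `[0, 1]`.
#' @export
render_scalogram <- function(s, out_size = 224, value_map = c("abs", "log-abs")) {
  value_map <- match.arg(value_map)
  check_number(out_size, "out_size", lower = 2)
  M <- abs(s$x)
  if (value_map == "log-abs") M <- log1p(M)
  M <- resample_bilinear(M, out_size, out_size)
  rng <- range(M)
  if (rng[2] <= rng[1]) return(matrix(0, out_size, out_size))
  M <- (M - rng[1]) / (rng[2] - rng[1])
  # flip so row 1 = highest frequency (top of the image)
  M[rev(seq_len(nrow(M))), , drop = FALSE]
}

# Separable bilinear resampling of a matrix to (nr, nc).
resample_bilinear <- function(M, nr, nc) {
  r0 <- seq(1, nrow(M), length.out = nr)
  c0 <- seq(1, ncol(M), length.out = nc)
  M1 <- apply(M, 2, function(col) approx(seq_len(nrow(M)), col, xout = r0)$y)
  M1 <- matrix(M1, nrow = nr)
  t(apply(M1, 1, function(row) approx(seq_len(ncol(M)), row, xout = c0)$y))
}

#' Write a rendered scalogram as an 8-bit grayscale PNG
#'
#' @param img Matrix in `[0, 1]` from [render_scalogram()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_scalogram_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("writing PNG requires the `png` package", call. = FALSE)
  }
  png::writePNG(img, path)
  invisible(path)
}
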