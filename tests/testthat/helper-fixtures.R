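# Shared fixtures: small synthetic configurations and reference signals.

tiny_synth <- function(n_subjects = 2L, minutes = 6L, apnea_fraction = 0.5,
                       seed = 42L, ...) {
  synth_config(n_subjects = n_subjects, minutes_per_subject = minutes,
               apnea_fraction = apnea_fraction, seed = seed, ...)
}

# 60 s two-tone mixture at 100 Hz: fast 5 Hz + slow 0.5 Hz, unit amplitudes.
two_tone <- function(fs = 100, dur = 60, f_fast = 5, f_slow = 0.5) {
  t <- (seq_len(fs * dur) - 1) / fs
  list(t = t, fast = sin(2 * pi * f_fast * t), slow = sin(2 * pi * f_slow * t),
       mix = sin(2 * pi * f_fast * t) + sin(2 * pi * f_slow * t))
}

# Interior indices excluding `frac`/2 of the samples at each end.
interior <- function(n, frac = 0.8) {
  k <- floor(n * (1 - frac) / 2)
  (k + 1):(n - k)
}

count_extrema <- function(y) {
  ex <- apneamodes:::find_extrema(y)
  length(ex$maxima) + length(ex$minima)
}
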