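#' Configuration for the synthetic apnea/normal ECG generator
#'
#' Defines the study conditions the generator emulates: overnight single-lead
#' ECG sampled at 100 Hz with per-minute apnea ('A') / normal ('N') labels.
#' Normal minutes carry a stable heart rate and stable QRS amplitude; apnea
#' minutes carry a cyclic bradycardia--tachycardia oscillation of the
#' instantaneous heart rate (period of tens of seconds) together with a QRS
#' amplitude modulation of the same period, the well-described ECG signature
#' of obstructive apnea episodes.
#'
#' The default `apnea_fraction` reproduces the class imbalance of the public
#' apnea ECG corpus this kind of screening is validated on
#' (6019 apnea / 15179 total minutes, about 0.397).
#'
#' @param n_subjects Number of subjects (recordings) to simulate.
#' @param minutes_per_subject Labeled minutes per recording.
#' @param apnea_fraction Fraction of minutes labeled apnea, in \[0, 1\].
#' @param fs Sampling rate in samples/s. Segments downstream are `60 * fs`
#'   samples long (6000 at the default 100 Hz).
#' @param hr_normal_bpm Heart rate during normal minutes (beats/min).
#' @param hr_apnea_low_bpm,hr_apnea_high_bpm Bounds of the cyclic heart-rate
#'   oscillation during apnea minutes; must bracket `hr_normal_bpm`.
#' @param apnea_cycle_s Period of the bradycardia--tachycardia cycle and the
#'   amplitude modulation, in seconds.
#' @param amp_mod_depth Relative depth of the QRS amplitude modulation during
#'   apnea minutes (0 = none).
#' @param baseline_wander_amp Amplitude of the additive low-frequency baseline
#'   wander, in mV.
#' @param noise_sd Standard deviation of additive white measurement noise, mV.
#' @param seed Integer seed; together with the subject index it fully
#'   determines every sample.
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L,
                         minutes_per_subject = 60L,
                         apnea_fraction = 6019 / 15179,
                         fs = 100,
                         hr_normal_bpm = 70,
                         hr_apnea_low_bpm = 50,
                         hr_apnea_high_bpm = 90,
                         apnea_cycle_s = 45,
                         amp_mod_depth = 0.3,
                         baseline_wander_amp = 0.05,
                         noise_sd = 0.02,
                         seed = 1L) {
  check_number(n_subjects, "n_subjects", lower = 1)
  check_number(minutes_per_subject, "minutes_per_subject", lower = 1)
  check_number(apnea_fraction, "apnea_fraction", lower = 0, upper = 1)
  check_number(fs, "fs", lower = 1)
  check_number(hr_normal_bpm, "hr_normal_bpm", lower = 1)
  check_number(hr_apnea_low_bpm, "hr_apnea_low_bpm", lower = 1)
  check_number(hr_apnea_high_bpm, "hr_apnea_high_bpm", lower = 1)
  check_number(apnea_cycle_s, "apnea_cycle_s", lower = 1)
  check_number(amp_mod_depth, "amp_mod_depth", lower = 0, upper = 1)
  check_number(baseline_wander_amp, "baseline_wander_amp", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  if (!(hr_apnea_low_bpm < hr_normal_bpm && hr_normal_bpm < hr_apnea_high_bpm)) {
    stop_config("hr_apnea_low_bpm",
      "must satisfy hr_apnea_low_bpm < hr_normal_bpm < hr_apnea_high_bpm")
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    minutes_per_subject = as.integer(minutes_per_subject),
    apnea_fraction = apnea_fraction,
    fs = fs,
    hr_normal_bpm = hr_normal_bpm,
    hr_apnea_low_bpm = hr_apnea_low_bpm,
    hr_apnea_high_bpm = hr_apnea_high_bpm,
    apnea_cycle_s = apnea_cycle_s,
    amp_mod_depth = amp_mod_depth,
    baseline_wander_amp = baseline_wander_amp,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synth_config")
}

# Fixed PQRST beat template: sum of 5 Gaussians over normalized beat time
# u in [0, 1). Centers/widths/amplitudes (mV) chosen to give a realistic
# monitoring-lead morphology with a dominant 1 mV R wave.
pqrst_template <- function() {
  list(
    center = c(P = 0.15, Q = 0.37, R = 0.40, S = 0.43, T = 0.70),
    width  = c(P = 0.030, Q = 0.012, R = 0.016, S = 0.012, T = 0.050),
    amp    = c(P = 0.12, Q = -0.15, R = 1.00, S = -0.25, T = 0.30)
  )
}

# Evaluate the beat template at fractional beat phases u (vectorized).
# Wrapped copies at u-1 and u+1 keep the waveform continuous across beats.
eval_pqrst <- function(u) {
  tpl <- pqrst_template()
  out <- numeric(length(u))
  for (g in seq_along(tpl$center)) {
    for (shift in c(-1, 0, 1)) {
      d <- u - tpl$center[[g]] + shift
      out <- out + tpl$amp[[g]] * exp(-d^2 / (2 * tpl$width[[g]]^2))
    }
  }
  out
}

#' Generate one synthetic ECG recording
#'
#' Synthesizes a continuous single-lead ECG for one subject. Minute labels are
#' drawn first (exactly `round(apnea_fraction * minutes)` apnea minutes at
#' seeded random positions); the waveform is then generated to match the
#' labels: apnea minutes receive a sinusoidal instantaneous-heart-rate
#' trajectory between the configured bounds with period `apnea_cycle_s`, plus
#' a QRS amplitude modulation of depth `amp_mod_depth`, while normal minutes
#' keep constant rate and amplitude. Baseline wander and white noise are added
#' on top. Output is bit-reproducible given `(config$seed, subject_index)`.
#'
#' @param config A [synth_config()].
#' @param subject_index 0-based subject index, `< config$n_subjects`.
#' @return An `ecg_record`: list with `subject_id`, `samples` (mV), `fs`, and
#'   `minute_labels` (character vector of "A"/"N").
#' @export
generate_record <- function(config, subject_index = 0L) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  check_number(subject_index, "subject_index", lower = 0,
    upper = config$n_subjects - 1)
  n_min <- config$minutes_per_subject
  fs <- config$fs
  n <- as.integer(round(n_min * 60 * fs))

  with_seed(derive_seed(config$seed, subject_index), {
    n_apnea <- as.integer(round(config$apnea_fraction * n_min))
    labels <- rep("N", n_min)
    if (n_apnea > 0L) labels[sample.int(n_min, n_apnea)] <- "A"

    tt <- (seq_len(n) - 1) / fs
    is_apnea <- rep(labels == "A", each = 60 * fs)

    hr_mid <- (config$hr_apnea_low_bpm + config$hr_apnea_high_bpm) / 2
    hr_amp <- (config$hr_apnea_high_bpm - config$hr_apnea_low_bpm) / 2
    phase_a <- runif(1, 0, 2 * pi)
    hr <- rep(config$hr_normal_bpm, n)
    hr[is_apnea] <- hr_mid +
      hr_amp * sin(2 * pi * tt[is_apnea] / config$apnea_cycle_s + phase_a)

    beat_phase <- cumsum(hr / (60 * fs))
    u <- beat_phase %% 1
    ecg <- eval_pqrst(u)

    amp_env <- rep(1, n)
    amp_env[is_apnea] <- 1 + config$amp_mod_depth *
      sin(2 * pi * tt[is_apnea] / config$apnea_cycle_s + phase_a)
    ecg <- ecg * amp_env

    if (config$baseline_wander_amp > 0) {
      phase_b <- runif(1, 0, 2 * pi)
      ecg <- ecg + config$baseline_wander_amp * sin(2 * pi * 0.25 * tt + phase_b)
    }
    if (config$noise_sd > 0) ecg <- ecg + rnorm(n, 0, config$noise_sd)

    new_ecg_record(
      subject_id = sprintf("s%02d", subject_index),
      samples = ecg, fs = fs, minute_labels = labels
    )
  })
}

#' Generate a synthetic apnea/normal ECG dataset
#'
#' @param config A [synth_config()].
#' @return List of `ecg_record`s with distinct subject ids.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  lapply(seq_len(config$n_subjects) - 1L, function(i) generate_record(config, i))
}

#' Construct an ECG record object
#'
#' @param subject_id Subject identifier string.
#' @param samples Numeric vector of ECG samples in mV.
#' @param fs Sampling rate, samples/s.
#' @param minute_labels Character vector of "A"/"N" per-minute labels.
#' @return List of class `ecg_record`.
#' @export
new_ecg_record <- function(subject_id, samples, fs, minute_labels) {
  if (!is.numeric(samples) || length(samples) == 0L) {
    stop("`samples` must be a nonempty numeric vector", call. = FALSE)
  }
  check_number(fs, "fs", lower = 1e-9)
  minute_labels <- as.character(minute_labels)
  if (length(minute_labels) && !all(minute_labels %in% c("A", "N"))) {
    stop("`minute_labels` must contain only 'A' and 'N'", call. = FALSE)
  }
  if (length(samples) < 60 * fs * length(minute_labels)) {
    stop(sprintf(
      "record '%s': %d samples cover fewer than the %d labeled minutes",
      subject_id, length(samples), length(minute_labels)), call. = FALSE)
  }
  structure(list(subject_id = as.character(subject_id),
                 samples = as.numeric(samples), fs = fs,
                 minute_labels = minute_labels),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %.1f min at %g Hz, %d labeled minutes (%d apnea)\n",
    x$subject_id, length(x$samples) / x$fs / 60, x$fs,
    length(x$minute_labels), sum(x$minute_labels == "A")))
  invisible(x)
}

#' R-peak based RR intervals of an ECG trace
#'
#' Audit utility for the synthetic generator: detects R peaks (local maxima
#' above half the trace maximum, at least 0.3 s apart) and returns successive
#' peak-to-peak intervals in seconds. Not part of the classification feature
#' path, which consumes decomposed raw signal rather than RR series.
#'
#' @param x Numeric ECG vector (mV).
#' @param fs Sampling rate, samples/s.
#' @return Numeric vector of RR intervals (s).
#' @export
rr_intervals <- function(x, fs) {
  pk <- find_peaks(x, min_height = 0.5 * max(x),
                   min_distance = as.integer(0.3 * fs))
  diff(pk) / fs
}
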