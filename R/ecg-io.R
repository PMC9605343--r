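#' Read and write ECG records with per-minute apnea annotations
#'
#' Two on-disk dialects are supported, both built from a base path (no
#' extension):
#'
#' * `wfdb`: PhysioNet-style single-signal record -- a text header
#'   `<base>.hea` (`name 1 fs n_samples` plus a signal line carrying the
#'   format-16 code and the gain in adu/mV), a little-endian 16-bit integer
#'   `<base>.dat`, and a plain-text annotation file `<base>.apn` with one
#'   label character ('A' or 'N') per labeled minute.
#' * `csv`: `<base>.csv` with columns `sample_index` (0-based), `value` (mV),
#'   and a JSON sidecar `<base>.json` holding `subject_id`, `fs`, and
#'   `minute_labels`. Lossless round-trip.
#'
#' Minute `m` (0-based) always covers samples `[m*60*fs, (m+1)*60*fs)`,
#' half-open. Records without an annotation file are rejected rather than
#' silently returned unlabeled.
#'
#' @name ecg_io
NULL

#' Write an ECG record
#'
#' @param record An `ecg_record` (see [new_ecg_record()]).
#' @param path Base file path without extension.
#' @param format `"csv"` (lossless) or `"wfdb"` (16-bit quantized).
#' @param gain WFDB gain in adu/mV; samples are stored as
#'   `round(value * gain)`, so the quantization error is at most `1/(2*gain)`.
#' @return Invisibly, the character vector of files written.
#' @export
write_ecg <- function(record, path, format = c("csv", "wfdb"), gain = 200) {
  format <- match.arg(format)
  if (!inherits(record, "ecg_record")) {
    stop("`record` must be an `ecg_record`", call. = FALSE)
  }
  if (length(record$samples) == 0L) stop("empty record", call. = FALSE)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (format == "csv") {
    csv <- paste0(path, ".csv")
    sidecar <- paste0(path, ".json")
    df <- data.frame(sample_index = seq_along(record$samples) - 1L,
                     value = record$samples)
    write.csv(df, csv, row.names = FALSE)
    jsonlite::write_json(
      list(subject_id = record$subject_id, fs = record$fs,
           minute_labels = record$minute_labels),
      sidecar, auto_unbox = TRUE, digits = NA)
    files <- c(csv, sidecar)
  } else {
    check_number(gain, "gain", lower = 1e-9)
    name <- basename(path)
    adu <- as.integer(round(record$samples * gain))
    if (any(adu > 32767L | adu < -32768L)) {
      stop("samples exceed the 16-bit range at this gain; lower `gain`",
           call. = FALSE)
    }
    hea <- paste0(path, ".hea")
    dat <- paste0(path, ".dat")
    apn <- paste0(path, ".apn")
    writeLines(c(
      sprintf("%s 1 %.10g %d", name, record$fs, length(adu)),
      sprintf("%s.dat 16 %.10g/mV 16 0 %d 0 0 ECG", name, gain, adu[1L])
    ), hea)
    con <- file(dat, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(adu, con, size = 2L, endian = "little")
    writeLines(record$minute_labels, apn)
    files <- c(hea, dat, apn)
  }
  invisible(files)
}

#' Read an ECG record
#'
#' @param path Base file path without extension.
#' @param format `"csv"` or `"wfdb"`.
#' @return An `ecg_record`.
#' @export
read_ecg <- function(path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  if (format == "csv") {
    csv <- paste0(path, ".csv")
    sidecar <- paste0(path, ".json")
    if (!file.exists(csv)) stop("missing file: ", csv, call. = FALSE)
    if (!file.exists(sidecar)) {
      stop("missing annotation sidecar: ", sidecar,
           " (records without labels are rejected)", call. = FALSE)
    }
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(meta$fs) || meta$fs <= 0) {
      stop("format error: sidecar `fs` missing or <= 0", call. = FALSE)
    }
    df <- read.csv(csv)
    new_ecg_record(meta$subject_id %||% basename(path), df$value,
                   as.numeric(meta$fs),
                   meta$minute_labels %||% character(0))
  } else {
    hea <- paste0(path, ".hea")
    dat <- paste0(path, ".dat")
    apn <- paste0(path, ".apn")
    if (!file.exists(hea)) stop("missing header: ", hea, call. = FALSE)
    if (!file.exists(dat)) stop("missing signal file: ", dat, call. = FALSE)
    if (!file.exists(apn)) {
      stop("missing annotation file: ", apn,
           " (records without labels are rejected)", call. = FALSE)
    }
    lines <- readLines(hea)
    rec <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
    fs <- suppressWarnings(as.numeric(rec[3L]))
    n <- suppressWarnings(as.integer(rec[4L]))
    if (!is.finite(fs) || fs <= 0) {
      stop("format error: sampling rate missing or <= 0 in ", hea,
           call. = FALSE)
    }
    sig <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
    if (sig[2L] != "16") {
      stop("unsupported WFDB format code: ", sig[2L], call. = FALSE)
    }
    gain <- as.numeric(sub("\\(.*\\)", "", sub("/.*$", "", sig[3L])))
    if (!is.finite(gain) || gain <= 0) gain <- 200
    con <- file(dat, "rb")
    on.exit(close(con), add = TRUE)
    adu <- readBin(con, "integer", n = n, size = 2L, endian = "little",
                   signed = TRUE)
    labels <- parse_annotations(apn)
    new_ecg_record(basename(path), adu / gain, fs, labels)
  }
}

# Annotation text -> label vector. Accepts one character per line or a single
# packed string like "ANA"; whitespace ignored.
parse_annotations <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- gsub("\\s", "", txt)
  labels <- strsplit(txt, "")[[1L]]
  bad <- setdiff(unique(labels), c("A", "N"))
  if (length(bad)) {
    stop("annotation file contains labels other than 'A'/'N': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  labels
}
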