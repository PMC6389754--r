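#' EEG segment container
#'
#' A channels x samples matrix of scalp potentials with sampling rate,
#' canonical 10-20 channel labels and 2-D electrode positions.
#'
#' @param data Numeric channels x samples matrix (microvolts), no NaN/NA.
#' @param fs Sampling rate in Hz (> 0).
#' @param labels Character vector of channel labels (unique), one per row.
#' @param xy Optional per-channel 2-D coordinates (mm); taken from the
#'   standard montage when omitted and labels are canonical.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(data, fs, labels = rownames(data), xy = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data) || any(!is.finite(data))) {
    stop("EEG data must be a finite numeric matrix")
  }
  stop_if_not_scalar_number(fs, "fs", 0, strict = TRUE)
  if (is.null(labels) || length(labels) != nrow(data)) {
    stop("one channel label per data row is required")
  }
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (ncol(data) < fs) stop("segment must be at least 1 s long")
  if (is.null(xy)) {
    lay <- montage_1020()
    idx <- match(labels, lay$labels)
    if (!anyNA(idx)) xy <- lay$xy[idx, , drop = FALSE]
  }
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels, xy = xy),
            class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("EEG segment: %d channels x %d samples (%.1f s at %g Hz)\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$fs, x$fs))
  cat("channels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# fixed-width ASCII field for EDF headers
.edf_field <- function(x, width) {
  s <- as.character(x)
  s <- vapply(s, function(si) {
    if (nchar(si) > width) si <- substr(si, 1, width)
    formatC(si, width = -width)
  }, character(1), USE.NAMES = FALSE)
  s
}

.edf_num <- function(x, width) {
  for (d in seq(7, 1)) {
    s <- formatC(signif(x, d), format = "g", digits = d)
    if (all(nchar(s) <= width)) break
  }
  .edf_field(s, width)
}

#' Write an EEG segment as EDF
#'
#' Writes a continuous European Data Format file with 16-bit samples, one
#' 1-second data record per second of signal, and per-channel physical
#' scaling chosen from the data range.
#'
#' @param seg An [eeg_segment()] whose duration is an integer number of
#'   seconds and whose sampling rate is an integer.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  fs <- seg$fs
  n <- ncol(seg$data)
  ns <- nrow(seg$data)
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  n_rec <- n / fs
  if (abs(n_rec - round(n_rec)) > 1e-9) {
    stop("EDF writer requires an integer number of seconds of signal")
  }
  n_rec <- as.integer(round(n_rec))

  phys_max <- apply(abs(seg$data), 1, max)
  phys_max <- ifelse(phys_max == 0, 1, phys_max * 1.0001)
  phys_max <- as.numeric(.edf_num(phys_max, 8))       # round-trippable in 8 chars
  phys_max <- pmax(phys_max, apply(abs(seg$data), 1, max))
  phys_min <- -phys_max
  dig_max <- 32767; dig_min <- -32768

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(paste0(s, collapse = ""), con, eos = NULL)
  wr(.edf_field("0", 8))
  wr(.edf_field("synthetic subject", 80))
  wr(.edf_field("synthetic resting EEG", 80))
  wr(.edf_field("01.01.26", 8))
  wr(.edf_field("00.00.00", 8))
  wr(.edf_field(256 + ns * 256, 8))
  wr(.edf_field("", 44))
  wr(.edf_field(n_rec, 8))
  wr(.edf_field(1, 8))
  wr(.edf_field(ns, 4))
  wr(.edf_field(seg$labels, 16))
  wr(.edf_field(rep("AgAgCl electrode", ns), 80))
  wr(.edf_field(rep("uV", ns), 8))
  wr(.edf_num(phys_min, 8))
  wr(.edf_num(phys_max, 8))
  wr(.edf_field(rep(dig_min, ns), 8))
  wr(.edf_field(rep(dig_max, ns), 8))
  wr(.edf_field(rep("", ns), 80))
  wr(.edf_field(rep(fs, ns), 8))
  wr(.edf_field(rep("", ns), 32))

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- round((seg$data[, cols, drop = FALSE] - phys_min) * scale + dig_min)
    block <- pmin(pmax(block, dig_min), dig_max)
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into an EEG segment
#'
#' Supports continuous recordings with a common integer sampling rate across
#' signals. Channel labels are normalized to canonical 10-20 names.
#'
#' @param path EDF file path.
#' @return An [eeg_segment()].
#' @export
read_eeg_edf <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nchars) trimws(readChar(con, nchars, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header length (recomputed below)
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1) stop(sprintf("malformed EDF header in %s", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)            # transducer
  for (i in seq_len(ns)) rd(8)             # dimension
  phys_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop(sprintf("mixed per-signal sampling rates in %s are not supported", path))
  }
  fs <- spr[1] / rec_dur
  out <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little", signed = TRUE)
    if (length(raw) < ns * spr[1]) stop(sprintf("truncated EDF file: %s", path))
    block <- matrix(raw, nrow = spr[1], ncol = ns)
    cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    out[, cols] <- t(block)
  }
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  out <- out * gain + (phys_min - dig_min * gain)
  labels <- normalize_channel_labels(labels)
  eeg_segment(out, fs = fs, labels = labels)
}

#' Write / read an EEG segment as delimited text
#'
#' The text dialect is a tab-separated table whose header row holds the
#' channel labels (one column per channel, one row per sample).
#'
#' @param seg An [eeg_segment()].
#' @param path File path.
#' @param fs Sampling rate to attach when reading (default 256 Hz).
#' @return `path` (writer) or an [eeg_segment()] (reader).
#' @export
write_eeg_delim <- function(seg, path) {
  stopifnot(inherits(seg, "eeg_segment"))
  utils::write.table(t(seg$data), path, sep = "\t", row.names = FALSE,
                     col.names = seg$labels, quote = FALSE)
  invisible(path)
}

#' @rdname write_eeg_delim
#' @export
read_eeg_delim <- function(path, fs = 256) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  labels <- normalize_channel_labels(colnames(tab))
  eeg_segment(t(as.matrix(tab)), fs = fs, labels = labels)
}

#' Read an EEG file, dispatching on extension
#'
#' `.edf` files are parsed as EDF; anything else is read as a delimited
#' channels-in-columns text matrix. Sampling rates other than the expected
#' one are rejected (resampling is out of scope).
#'
#' @param path File path.
#' @param fs Expected sampling rate (Hz).
#' @return An [eeg_segment()].
#' @export
read_eeg <- function(path, fs = 256) {
  seg <- if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    read_eeg_edf(path)
  } else {
    read_eeg_delim(path, fs = fs)
  }
  if (abs(seg$fs - fs) > 1e-9) {
    stop(sprintf("%s is sampled at %g Hz, expected %g Hz; resampling is not supported",
                 path, seg$fs, fs))
  }
  seg
}

.covariate_columns <- c("subject_id", "group", "syndrome", "seizure_control",
                        "age", "gender", "aed_load", "seizure_count_12m")

#' Write / read a cohort covariate table
#'
#' Tab-separated text with a header; required columns are `subject_id`,
#' `group`, `syndrome`, `seizure_control`, `age`, `gender`, `aed_load` and
#' `seizure_count_12m`.
#'
#' @param table A `cohort_table` data frame.
#' @param path File path.
#' @return `path` (writer) or a `cohort_table` (reader).
#' @export
write_covariates <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_covariates
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(.covariate_columns, colnames(tab))
  if (length(missing)) {
    stop(sprintf("covariate table %s is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(tab$subject_id)) {
    stop(sprintf("duplicate subject_id values in %s", path))
  }
  if (!is.numeric(tab$age) || !is.numeric(tab$aed_load) ||
      !is.numeric(tab$seizure_count_12m)) {
    stop(sprintf("age, aed_load and seizure_count_12m must be numeric in %s", path))
  }
  class(tab) <- c("cohort_table", "data.frame")
  tab
}
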