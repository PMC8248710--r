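STANDARD_SR <- 4000L
STANDARD_SAMPLES <- 60000L
EVENT_CLASSES <- c("I", "E", "W", "S", "R", "D")

#' Construct a lung sound recording object
#'
#' A `lung_recording` holds a mono waveform with amplitudes in `[-1, 1]`,
#' its sampling rate and an identifier. All pipeline inputs are 4 kHz; the
#' standard recording length is 15 s (60,000 samples).
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`.
#' @param sample_rate sampling rate in Hz.
#' @param id recording identifier string.
#' @param source origin tag: `"steth"` (electronic stethoscope),
#'   `"trunc"` (truncated multichannel device recording) or `"synth"`.
#' @return an object of class `lung_recording`.
#' @export
lung_recording <- function(samples, sample_rate = STANDARD_SR, id = "rec",
                           source = c("synth", "steth", "trunc")) {
  source <- match.arg(source)
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) {
    stop("recording amplitudes must be finite")
  }
  structure(
    list(samples = samples, sample_rate = as.integer(sample_rate),
         id = as.character(id), source = source),
    class = "lung_recording"
  )
}

#' @export
print.lung_recording <- function(x, ...) {
  cat(sprintf("<lung_recording> id=%s source=%s %d samples @ %d Hz (%.3f s)\n",
              x$id, x$source, length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate))
  invisible(x)
}

#' @export
length.lung_recording <- function(x) length(x$samples)

# -- RIFF/WAVE ---------------------------------------------------------------
# Minimal PCM WAVE reader/writer (16-bit mono). Chunk-walks the RIFF
# container; duration is always validated by sample count, never by header
# metadata alone.

read_uint32 <- function(con) readBin(con, "integer", 1, size = 4, endian = "little")
read_uint16 <- function(con) {
  v <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = "little")
  v
}

#' Read a PCM WAVE file
#'
#' Reads a 16-bit PCM mono WAVE file and maps the integer samples to
#' `[-1, 1]` by dividing by 32768 (symmetric full-scale convention).
#' Stereo files, non-PCM encodings and unexpected sampling rates are
#' rejected; no silent resampling is performed.
#'
#' @param path path to a `.wav` file.
#' @param id recording identifier; defaults to the file name without extension.
#' @param source source tag stored on the recording.
#' @param expected_rate required sampling rate in Hz; `NULL` skips the check.
#' @return a [lung_recording].
#' @export
read_wav <- function(path, id = NULL, source = "steth", expected_rate = STANDARD_SR) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  read_uint32(con)
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    tag <- readChar(con, 4, useBytes = TRUE)
    if (length(tag) == 0 || nchar(tag) < 4) break
    size <- read_uint32(con)
    if (identical(tag, "fmt ")) {
      fmt <- list(
        audio_format = read_uint16(con),
        n_channels = read_uint16(con),
        sample_rate = read_uint32(con),
        byte_rate = read_uint32(con),
        block_align = read_uint16(con),
        bits_per_sample = read_uint16(con)
      )
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAVE file: ", path)
  if (fmt$audio_format != 1L) stop("unsupported encoding (not PCM): format tag ", fmt$audio_format)
  if (fmt$n_channels != 1L) stop("unsupported channel count: ", fmt$n_channels, " (mono required)")
  if (fmt$bits_per_sample != 16L) stop("unsupported bit depth: ", fmt$bits_per_sample, " (16-bit required)")
  if (!is.null(expected_rate) && fmt$sample_rate != expected_rate) {
    stop("unexpected sample rate: ", fmt$sample_rate, " Hz (expected ", expected_rate, " Hz)")
  }
  ints <- readBin(data_raw, "integer", n = length(data_raw) / 2, size = 2,
                  signed = TRUE, endian = "little")
  if (is.null(id)) id <- sub("\\.wav$", "", basename(path), ignore.case = TRUE)
  lung_recording(ints / 32768, fmt$sample_rate, id = id, source = source)
}

#' Write a recording as a 16-bit PCM mono WAVE file
#'
#' Amplitudes are clipped to `[-1, 1)` and scaled by 32768; the inverse of
#' [read_wav()] up to quantization.
#'
#' @param rec a [lung_recording].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path) {
  stopifnot(inherits(rec, "lung_recording"))
  x <- pmin(pmax(rec$samples, -1), 32767 / 32768)
  ints <- as.integer(round(x * 32768))
  n <- length(ints)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")   # PCM
  writeBin(1L, con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rec$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$sample_rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(ints, con, size = 2, endian = "little")
  invisible(path)
}

# -- Truncation protocols ----------------------------------------------------

#' Truncate a 15.8-s stethoscope recording to 15 s
#'
#' Electronic-stethoscope files are 15.8 s long (63,200 samples at 4 kHz);
#' the final 0.8 s is cropped, keeping the first 60,000 samples. Durations
#' are validated by sample count.
#'
#' @param rec a [lung_recording] with exactly 63,200 samples.
#' @return a 60,000-sample [lung_recording] at the same rate.
#' @export
truncate_littmann <- function(rec) {
  stopifnot(inherits(rec, "lung_recording"))
  if (length(rec$samples) != 63200L) {
    stop("unexpected duration: ", length(rec$samples),
         " samples (expected 63,200 = 15.8 s at 4 kHz)")
  }
  lung_recording(rec$samples[seq_len(STANDARD_SAMPLES)], rec$sample_rate,
                 id = rec$id, source = "steth")
}

#' Keep the first 15 s of a long multichannel-device recording
#'
#' The multichannel device records 2-minute segments; only the first 15 s
#' (60,000 samples) is used. Any recording of at least 15 s is accepted.
#'
#' @param rec a [lung_recording] of duration >= 15 s.
#' @return a 60,000-sample [lung_recording] at the same rate.
#' @export
truncate_hftype1 <- function(rec) {
  stopifnot(inherits(rec, "lung_recording"))
  if (length(rec$samples) < STANDARD_SAMPLES) {
    stop("too short: ", length(rec$samples),
         " samples (need at least 60,000 = 15 s at 4 kHz)")
  }
  lung_recording(rec$samples[seq_len(STANDARD_SAMPLES)], rec$sample_rate,
                 id = rec$id, source = "trunc")
}

# -- Event labels ------------------------------------------------------------

#' Construct an event label table
#'
#' Events are stored as a data frame with columns `onset`, `offset`
#' (seconds) and `class` (one of I, E, W, S, R, D). CAS is never stored as a
#' class of its own: it is derived downstream as the union of W, S and R.
#'
#' @param onset,offset numeric vectors of event boundaries in seconds.
#' @param class character vector of class tokens.
#' @return a data frame of class `lung_events`, sorted by onset.
#' @export
lung_events <- function(onset = numeric(), offset = numeric(), class = character()) {
  stopifnot(length(onset) == length(offset), length(onset) == length(class))
  class <- as.character(class)
  bad <- !class %in% EVENT_CLASSES
  if (any(bad)) stop("unknown event class: ", paste(unique(class[bad]), collapse = ", "))
  if (any(offset <= onset)) stop("event offset must exceed onset")
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset),
                   class = class, stringsAsFactors = FALSE)
  df <- df[order(df$onset, df$offset, df$class), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("lung_events", "data.frame"))
}

#' Read an event-label file
#'
#' Label files are headerless tab-separated text with one event per line:
#' onset seconds, offset seconds, class token (I, E, W, S, R or D). Events
#' are sorted by onset on read. Overlapping same-class events are permitted
#' (e.g. abutting crackle trains); a non-positive duration is a parse error
#' reported with its line number.
#'
#' @param path path to a label TSV.
#' @return a [lung_events] table.
#' @export
read_labels <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(lung_events())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  onset <- numeric(length(parts)); offset <- numeric(length(parts))
  cls <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop("malformed label line ", i, ": ", lines[i])
    onset[i] <- suppressWarnings(as.numeric(p[1]))
    offset[i] <- suppressWarnings(as.numeric(p[2]))
    cls[i] <- trimws(p[3])
    if (is.na(onset[i]) || is.na(offset[i])) {
      stop("non-numeric time on label line ", i, ": ", lines[i])
    }
    if (offset[i] <= onset[i]) {
      stop("offset <= onset on label line ", i, ": ", lines[i])
    }
  }
  lung_events(onset, offset, cls)
}

#' Write an event-label file
#'
#' Inverse of [read_labels()]: headerless TSV, times formatted with
#' millisecond (or better) precision so a write/read round trip is the
#' identity on sorted event lists.
#'
#' @param events a [lung_events] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(events, path) {
  stopifnot(is.data.frame(events))
  lines <- sprintf("%.6f\t%.6f\t%s", events$onset, events$offset, events$class)
  writeLines(lines, path)
  invisible(path)
}

#' Pool raw label classes for a detection task
#'
#' Tasks are I (inhalation), E (exhalation), CAS (union of wheeze W,
#' stridor S and rhonchus R) and DAS (crackles, class D).
#'
#' @param events a [lung_events] table.
#' @param task one of `"I"`, `"E"`, `"CAS"`, `"DAS"`.
#' @return the subset of `events` belonging to the task.
#' @export
task_events <- function(events, task = c("I", "E", "CAS", "DAS")) {
  task <- match.arg(task)
  keep <- switch(task,
    I = events$class == "I",
    E = events$class == "E",
    CAS = events$class %in% c("W", "S", "R"),
    DAS = events$class == "D")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
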