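#' Read a recorded intensity time-series from disk
#'
#' Supported formats:
#' * `text` -- one sample per line (plain numbers);
#' * `csv` -- a single-column CSV (with or without a header row);
#' * `wav` -- 16-bit mono PCM WAV; samples are returned as the raw
#'   signed 16-bit integers written by the acquisition system, without
#'   rescaling, and the sampling rate is taken from the header.
#'
#' @param path File path.
#' @param format One of `"auto"` (by extension), `"text"`, `"csv"`,
#'   `"wav"`.
#' @param sampling_frequency Sampling rate (Hz); required for text/CSV,
#'   ignored for WAV (the header wins, with a warning on conflict).
#' @return A [dls_time_series()] with origin `"recorded"`.
#' @export
read_series_file <- function(path, format = c("auto", "text", "csv", "wav"),
                             sampling_frequency = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     wav = "wav", csv = "csv", "text")
  }
  if (format == "wav") {
    w <- read_wav_mono16(path)
    if (!is.null(sampling_frequency) &&
        sampling_frequency != w$sample_rate) {
      warning(sprintf(
        "WAV header says %d Hz; ignoring supplied sampling_frequency = %g",
        w$sample_rate, sampling_frequency))
    }
    return(dls_time_series(w$samples, w$sample_rate, origin = "recorded"))
  }
  if (is.null(sampling_frequency)) {
    stop("`sampling_frequency` is required for text/CSV series files",
         call. = FALSE)
  }
  samples <- if (format == "csv") {
    df <- read.csv(path, header = csv_has_header(path))
    if (ncol(df) != 1L) {
      stop(sprintf("series CSV must have exactly 1 column, found %d: %s",
                   ncol(df), path), call. = FALSE)
    }
    df[[1L]]
  } else {
    txt <- readLines(path, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) == 0L) stop("empty series file: ", path, call. = FALSE)
    vals <- suppressWarnings(as.numeric(txt))
    if (any(is.na(vals))) {
      bad <- which(is.na(vals))[1L]
      stop(sprintf("malformed sample on line %d of %s: '%s'", bad, path,
                   txt[bad]), call. = FALSE)
    }
    vals
  }
  if (!is.numeric(samples) || any(is.na(samples))) {
    stop("series file contains non-numeric samples: ", path, call. = FALSE)
  }
  dls_time_series(samples, sampling_frequency, origin = "recorded")
}

csv_has_header <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1L]][1L])))
}

#' Write a time-series to disk
#'
#' Inverse of [read_series_file()] for the `text` and `wav` formats
#' (WAV output is 16-bit mono PCM; samples must already be integers in
#' the signed 16-bit range).
#'
#' @param series A [dls_time_series()].
#' @param path Output path.
#' @param format `"text"` or `"wav"` (default by extension).
#' @return `path`, invisibly.
#' @export
write_series_file <- function(series, path,
                              format = c("auto", "text", "wav")) {
  stopifnot(inherits(series, "dls_time_series"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "wav") "wav" else "text"
  }
  if (format == "wav") {
    write_wav_mono16(series$samples, series$sampling_frequency, path)
  } else {
    writeLines(format(series$samples, scientific = FALSE, trim = TRUE,
                      digits = 15), path)
  }
  invisible(path)
}

## Minimal RIFF/WAVE PCM reader, restricted to what a DLS acquisition
## writes: uncompressed 16-bit samples. Returns integers exactly as
## stored. Rejects anything but mono.
read_wav_mono16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", size)
      to_int <- function(bytes) sum(as.integer(bytes) * 256^(seq_along(bytes) - 1L))
      fmt <- list(audio_format = to_int(raw_fmt[1:2]),
                  channels = to_int(raw_fmt[3:4]),
                  sample_rate = to_int(raw_fmt[5:8]),
                  bits = to_int(raw_fmt[15:16]))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("WAV data chunk precedes fmt chunk", call. = FALSE)
      if (fmt$audio_format != 1L) {
        stop("only uncompressed PCM WAV is supported", call. = FALSE)
      }
      if (fmt$channels != 1L) {
        stop(sprintf("WAV must be mono; found %d channels", fmt$channels),
             call. = FALSE)
      }
      if (fmt$bits != 16L) {
        stop(sprintf("WAV must be 16-bit; found %d-bit", fmt$bits),
             call. = FALSE)
      }
      samples <- readBin(con, "integer", n = size %/% 2L, size = 2L,
                         signed = TRUE, endian = "little")
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1L))  # chunk padding
  }
  if (is.null(samples)) stop("WAV file has no data chunk: ", path, call. = FALSE)
  list(samples = samples, sample_rate = fmt$sample_rate)
}

write_wav_mono16 <- function(samples, sample_rate, path, channels = 1L) {
  if (any(samples != round(samples)) ||
      any(samples < -32768) || any(samples > 32767)) {
    stop("WAV output requires integer samples in [-32768, 32767]",
         call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(samples) * 2L
  w_int <- function(x, size) {
    writeBin(as.integer(x), con, size = size, endian = "little")
  }
  writeChar("RIFF", con, eos = NULL)
  w_int(36L + n_bytes, 4L)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w_int(16L, 4L)
  w_int(1L, 2L)                              # PCM
  w_int(channels, 2L)
  w_int(sample_rate, 4L)
  w_int(sample_rate * channels * 2L, 4L)     # byte rate
  w_int(channels * 2L, 2L)                   # block align
  w_int(16L, 2L)                             # bits per sample
  writeChar("data", con, eos = NULL)
  w_int(n_bytes, 4L)
  w_int(samples, 2L)
  invisible(path)
}
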