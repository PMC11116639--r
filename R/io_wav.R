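#' Audio recording container
#'
#' A mono sampled waveform: the raw input signal of the pipeline. Samples are
#' real-valued amplitudes in \[-1, 1\].
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param sample_rate Sampling rate in Hz (positive integer).
#' @return An object of class `audio_recording` with fields `samples`,
#'   `sample_rate`, `n_samples`, and `duration_s`.
#' @examples
#' rec <- audio_recording(sin(2 * pi * 100 * (0:7999) / 8000), 8000)
#' rec$duration_s
#' @export
audio_recording <- function(samples, sample_rate) {
  samples <- as.numeric(samples)
  sample_rate <- as.integer(sample_rate)
  if (length(sample_rate) != 1L || is.na(sample_rate) || sample_rate <= 0L)
    stop("sample_rate must be a single positive integer", call. = FALSE)
  if (anyNA(samples)) stop("samples must not contain NA", call. = FALSE)
  structure(
    list(samples = samples, sample_rate = sample_rate,
         n_samples = length(samples),
         duration_s = length(samples) / sample_rate),
    class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %d Hz (%.1f s)\n",
              x$n_samples, x$sample_rate, x$duration_s))
  invisible(x)
}

# Internal: read a RIFF chunk header (4-char id + uint32 size).
read_chunk_header <- function(con) {
  id <- readChar(con, 4L, useBytes = TRUE)
  size <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(size) == 0L) return(NULL)
  list(id = id, size = size)
}

#' Read a mono PCM WAV file
#'
#' Parses the RIFF/WAVE container directly. Only uncompressed linear PCM
#' (format tag 1) with a single channel is accepted; 8-bit (unsigned) and
#' 16-bit (signed) sample widths are supported. Samples are scaled to
#' \[-1, 1\] by dividing by the full-scale value (128 for 8-bit, 32768 for
#' 16-bit). No resampling is performed: the header sample rate is reported
#' as-is so that rate mismatches surface rather than hide.
#'
#' @param path Path to a WAV file.
#' @return An [audio_recording].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  readBin(con, "integer", 1L, 4L, endian = "little")  # overall size
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL
  samples <- NULL
  repeat {
    hdr <- read_chunk_header(con)
    if (is.null(hdr) || !nzchar(hdr$id)) break
    if (hdr$id == "fmt ") {
      raw <- readBin(con, "raw", n = hdr$size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1L, 4L, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1L, 2L, signed = FALSE,
                               endian = "little"))
    } else if (hdr$id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt", call. = FALSE)
      if (fmt$audio_format != 1L)
        stop("unsupported WAV format: audio_format=", fmt$audio_format,
             " (only uncompressed PCM, format 1, is supported)", call. = FALSE)
      if (fmt$n_channels != 1L)
        stop("unsupported WAV format: n_channels=", fmt$n_channels,
             " (only mono recordings are supported)", call. = FALSE)
      bytes_per <- fmt$bits %/% 8L
      n <- hdr$size %/% bytes_per
      if (fmt$bits == 16L) {
        ints <- readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                        endian = "little")
        samples <- ints / 32768
      } else if (fmt$bits == 8L) {
        ints <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
        samples <- (ints - 128) / 128
      } else {
        stop("unsupported WAV format: bits_per_sample=", fmt$bits,
             " (only 8 or 16 bit PCM)", call. = FALSE)
      }
    } else {
      # skip unknown chunk (word-aligned)
      seek(con, hdr$size + hdr$size %% 2L, origin = "current")
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("malformed WAV: no data chunk in ", path,
                             call. = FALSE)
  audio_recording(samples, fmt$sample_rate)
}

#' Write a mono PCM WAV file
#'
#' Quantizes samples to the requested bit depth (values clipped to \[-1, 1\])
#' and writes a canonical 44-byte-header RIFF/WAVE PCM file.
#'
#' @param rec An [audio_recording].
#' @param path Output path.
#' @param bits Sample width: 8 or 16 (default).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16L) {
  stopifnot(inherits(rec, "audio_recording"))
  bits <- as.integer(bits)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16", call. = FALSE)
  x <- pmin(1, pmax(-1, rec$samples))
  bytes_per <- bits %/% 8L
  data_size <- rec$n_samples * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(rec$sample_rate, con, size = 4L, endian = "little")
  writeBin(rec$sample_rate * bytes_per, con, size = 4L, endian = "little")
  writeBin(bytes_per, con, size = 2L, endian = "little")     # block align
  writeBin(bits, con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bits == 16L) {
    ints <- as.integer(pmin(32767, pmax(-32768, round(x * 32768))))
    writeBin(ints, con, size = 2L, endian = "little")
  } else {
    ints <- as.integer(pmin(255, pmax(0, round(x * 128) + 128)))
    writeBin(ints, con, size = 1L)
  }
  invisible(path)
}

#' Split a recording into hour-long segments
#'
#' Cuts a night into consecutive non-overlapping 3600-s segments. A trailing
#' partial segment is kept (and flagged) so nights shorter than a whole
#' number of hours remain gradable; concatenating the segments reproduces
#' the input exactly.
#'
#' @param rec An [audio_recording] of duration at least 1 s.
#' @return A list of [audio_recording] segments, each with attribute
#'   `partial` (TRUE for a trailing segment shorter than one hour).
#' @export
segment_hours <- function(rec) {
  stopifnot(inherits(rec, "audio_recording"))
  if (rec$duration_s < 1) stop("recording shorter than 1 s", call. = FALSE)
  hour_n <- 3600L * rec$sample_rate
  starts <- seq(1L, rec$n_samples, by = hour_n)
  lapply(starts, function(s) {
    e <- min(s + hour_n - 1L, rec$n_samples)
    seg <- audio_recording(rec$samples[s:e], rec$sample_rate)
    attr(seg, "partial") <- (e - s + 1L) < hour_n
    seg
  })
}
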