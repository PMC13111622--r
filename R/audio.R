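# Stimulus pre-processing: midpoint snippet extraction, RMS amplitude
# normalization and downsampling (default 8 kHz, the telephone-band rate
# common in forensic casework). Operates on in-memory waveforms; minimal
# PCM16 WAV read/write is provided for interchange.

#' Construct an audio snippet
#'
#' @param samples Numeric vector of amplitudes, nominally in `[-1, 1]`.
#' @param rate Sampling rate in Hz.
#' @param source_id Optional identifier of the source recording.
#' @return A list of class `audio_snippet` with elements `samples`,
#'   `rate`, `source_id`.
#' @export
audio_snippet <- function(samples, rate, source_id = NA_character_) {
  stopifnot(is.numeric(samples), length(samples) > 0,
            is.numeric(rate), rate > 0)
  structure(list(samples = as.numeric(samples), rate = rate,
                 source_id = source_id),
            class = "audio_snippet")
}

#' Extract a fixed-duration snippet centred on the signal midpoint
#'
#' @param signal An `audio_snippet` (or numeric vector with `rate`).
#' @param duration_s Snippet duration in seconds (default 1.2).
#' @param rate Sampling rate, required when `signal` is a bare vector.
#' @return An `audio_snippet` of `round(duration_s * rate)` samples.
#' @export
extract_midpoint <- function(signal, duration_s = 1.2, rate = NULL) {
  if (!inherits(signal, "audio_snippet"))
    signal <- audio_snippet(signal, rate)
  n_out <- round(duration_s * signal$rate)
  n <- length(signal$samples)
  if (n < n_out)
    abort("signal of %.3f s is shorter than the requested %.3f s snippet",
          n / signal$rate, duration_s)
  start <- floor((n - n_out) / 2)
  audio_snippet(signal$samples[(start + 1):(start + n_out)], signal$rate,
                signal$source_id)
}

rms <- function(x) sqrt(mean(x^2))

#' Normalize a snippet to a target RMS level
#'
#' The target is expressed in dB against a configurable full-scale
#' reference: a target of `target_db` corresponds to a linear RMS of
#' `10^((target_db - dbfs_offset) / 20)` on the `[-1, 1]` digital scale.
#' With the default offset of 100, 65 dB maps to -35 dBFS RMS. The gain
#' applied is `target_rms / input_rms` (pure linear scaling).
#'
#' @param snippet An `audio_snippet`.
#' @param target_db Target level in dB (default 65).
#' @param dbfs_offset dB value assigned to digital full scale
#'   (default 100).
#' @return The normalized `audio_snippet`.
#' @export
rms_normalize <- function(snippet, target_db = 65, dbfs_offset = 100) {
  stopifnot(inherits(snippet, "audio_snippet"))
  r <- rms(snippet$samples)
  if (r == 0)
    abort("cannot normalize an all-zero signal (undefined gain)")
  target_rms <- 10^((target_db - dbfs_offset) / 20)
  audio_snippet(snippet$samples * (target_rms / r), snippet$rate,
                snippet$source_id)
}

#' Resample a snippet to a target rate
#'
#' Band-limited polyphase resampling via [signal::resample()]; a pure
#' tone below the target Nyquist keeps its frequency. Output length is
#' `ceiling(n * target_rate / rate)`.
#'
#' @param snippet An `audio_snippet`.
#' @param target_rate Target sampling rate in Hz (default 8000).
#' @param allow_upsampling Permit `target_rate > rate` (default `FALSE`).
#' @return The resampled `audio_snippet`.
#' @export
resample_snippet <- function(snippet, target_rate = 8000,
                             allow_upsampling = FALSE) {
  stopifnot(inherits(snippet, "audio_snippet"))
  if (target_rate == snippet$rate) return(snippet)
  if (target_rate > snippet$rate && !allow_upsampling)
    abort("upsampling from %g to %g Hz is disabled", snippet$rate, target_rate)
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  g <- gcd(as.integer(target_rate), as.integer(snippet$rate))
  y <- signal::resample(snippet$samples,
                        as.integer(target_rate) %/% g,
                        as.integer(snippet$rate) %/% g)
  audio_snippet(as.numeric(y), target_rate, snippet$source_id)
}

#' Run the full snippet preparation pipeline
#'
#' Midpoint extraction, RMS normalization, then downsampling — the
#' standard preparation of 1.2 s sentence snippets.
#'
#' @inheritParams extract_midpoint
#' @inheritParams rms_normalize
#' @inheritParams resample_snippet
#' @return An `audio_snippet` at `target_rate`.
#' @export
prepare_snippet <- function(signal, duration_s = 1.2, rate = NULL,
                            target_db = 65, dbfs_offset = 100,
                            target_rate = 8000) {
  s <- extract_midpoint(signal, duration_s, rate)
  s <- rms_normalize(s, target_db, dbfs_offset)
  resample_snippet(s, target_rate)
}

#' Write a snippet as 16-bit PCM mono WAV
#'
#' @param snippet An `audio_snippet`; samples are clipped to `[-1, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(snippet, path) {
  stopifnot(inherits(snippet, "audio_snippet"))
  x <- pmax(-1, pmin(1, snippet$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_len <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")              # PCM
  writeBin(1L, con, size = 2, endian = "little")              # mono
  writeBin(as.integer(snippet$rate), con, size = 4, endian = "little")
  writeBin(as.integer(snippet$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")              # block align
  writeBin(16L, con, size = 2, endian = "little")             # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM mono WAV file
#'
#' @param path Path to a WAV file written by [write_wav()] or any plain
#'   PCM16 mono WAV.
#' @return An `audio_snippet` with samples scaled to `[-1, 1]`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) abort("input file not found: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (riff != "RIFF" || wave != "WAVE") abort("not a RIFF/WAVE file: %s", path)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("no data chunk in %s", path)
    len <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L)
        abort("only mono PCM WAV is supported")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      readBin(con, "raw", len - 8)
    } else if (id == "data") {
      pcm <- readBin(con, "integer", len / 2, size = 2, endian = "little",
                     signed = TRUE)
      break
    } else {
      readBin(con, "raw", len)
    }
  }
  audio_snippet(pcm / 32767, rate, source_id = basename(path))
}
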