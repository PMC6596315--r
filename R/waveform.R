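#' Construct a waveform object
#'
#' A `tone_wave` is a mono sampled audio signal: a numeric vector of
#' amplitudes in \[-1, 1\] plus a sampling rate in Hz. It is the unit of
#' synthesis and analysis throughout the package.
#'
#' @param samples Numeric vector of amplitudes; must be finite.
#' @param rate Sampling rate in Hz (default 44100, the recording rate used
#'   for the production task).
#' @return A `tone_wave` object.
#' @export
waveform <- function(samples, rate = 44100) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples))) {
    stop("samples must be finite numeric values")
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number")
  }
  structure(list(samples = as.numeric(samples), rate = as.numeric(rate)),
            class = "tone_wave")
}

#' @export
print.tone_wave <- function(x, ...) {
  cat(sprintf("<tone_wave: %d samples @ %g Hz (%.1f ms), peak %.3f>\n",
              length(x$samples), x$rate,
              1000 * length(x$samples) / x$rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in milliseconds
#' @param wave A `tone_wave`.
#' @return Duration in ms.
#' @export
wave_duration_ms <- function(wave) 1000 * length(wave$samples) / wave$rate

#' RMS level of a waveform in dB full scale
#'
#' @param wave A `tone_wave`.
#' @param floor_db Value returned for silent input (default -100).
#' @return RMS level in dBFS (0 dB = full-scale constant signal).
#' @export
wave_rms_db <- function(wave, floor_db = -100) {
  ms <- mean(wave$samples^2)
  if (ms <= 0) return(floor_db)
  max(10 * log10(ms), floor_db)
}

#' Read a PCM WAV file
#'
#' Supports uncompressed PCM, 16- or 24-bit, mono or stereo. Stereo input is
#' mixed down to mono with a warning. Only plain RIFF/WAVE with `fmt ` and
#' `data` chunks is handled; anything else is rejected with an explicit error.
#'
#' @param path Path to a `.wav` file.
#' @return A `tone_wave`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      if (length(body) < 16L) stop("truncated fmt chunk in ", path)
      u16 <- function(i) sum(as.integer(body[i:(i + 1)]) * c(1L, 256L))
      u32 <- function(i) sum(as.numeric(body[i:(i + 3)]) * 256^(0:3))
      fmt <- list(audio_format = u16(1), channels = u16(3),
                  rate = u32(5), bits = u16(15))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (length(data_raw) < size) stop("truncated data chunk in ", path)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("missing fmt/data chunk in ", path)
  if (fmt$audio_format != 1L) stop("unsupported WAV encoding (non-PCM) in ", path)
  if (!fmt$bits %in% c(16L, 24L)) stop("unsupported bit depth: ", fmt$bits)

  bytes_per <- fmt$bits / 8L
  n <- length(data_raw) %/% bytes_per
  if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little")
    x <- x / 32768
  } else {
    b <- as.integer(data_raw[seq_len(n * 3L)])
    dim(b) <- c(3L, n)
    v <- b[1L, ] + b[2L, ] * 256 + b[3L, ] * 65536
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    x <- v / 8388608
  }
  if (fmt$channels > 1L) {
    warning("stereo WAV mixed down to mono: ", path)
    nfr <- length(x) %/% fmt$channels
    dim(x) <- c(fmt$channels, nfr)
    x <- colMeans(x)
  }
  waveform(x, fmt$rate)
}

#' Write a waveform as a 16-bit PCM WAV file
#'
#' Samples are clipped to \[-1, 1) and quantized to 16 bits; the round trip
#' through [read_wav()] is exact to within one least-significant bit.
#'
#' @param wave A `tone_wave`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(wave, path) {
  stopifnot(inherits(wave, "tone_wave"))
  x <- pmax(pmin(wave$samples, 1 - 1 / 32768), -1)
  q <- as.integer(round(x * 32768))
  q <- pmax(pmin(q, 32767L), -32768L)
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  wchar <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  wchar("RIFF"); w32(36L + n_bytes); wchar("WAVE")
  wchar("fmt "); w32(16L); w16(1L); w16(1L)
  w32(as.integer(round(wave$rate))); w32(as.integer(round(wave$rate)) * 2L)
  w16(2L); w16(16L)
  wchar("data"); w32(n_bytes)
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}
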