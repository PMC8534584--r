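#' Phonation container
#'
#' A phonation is a mono audio signal with its sampling rate and optional
#' per-recording metadata (participant id, class label, age, gender). Samples
#' are stored as doubles in \[-1, 1\] regardless of the on-disk bit depth.
#'
#' @param samples Numeric vector of audio samples in \[-1, 1\].
#' @param fs Sampling rate in Hz.
#' @param meta Named list of recording metadata (may be empty).
#' @return An object of class `phonation`.
#' @export
phonation <- function(samples, fs, meta = list()) {
  stopifnot(is.numeric(samples), length(samples) > 0, is.numeric(fs), fs > 0)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs), meta = meta),
    class = "phonation"
  )
}

#' @export
print.phonation <- function(x, ...) {
  cat(sprintf("<phonation> %.3f s at %g Hz (%d samples)\n",
              length(x$samples) / x$fs, x$fs, length(x$samples)))
  invisible(x)
}

#' Duration of a phonation in seconds
#' @param p A `phonation`.
#' @return Duration in seconds.
#' @export
duration <- function(p) length(p$samples) / p$fs

#' Read a RIFF WAV file as a phonation
#'
#' Reads PCM WAV (8- or 16-bit). Multi-channel input is downmixed to mono by
#' channel averaging with a warning. Integer samples are scaled to \[-1, 1\]
#' by the PCM convention (16-bit: x / 32768).
#'
#' @param path Path to a RIFF WAV file.
#' @return A `phonation`.
#' @export
read_phonation <- function(path) {
  con <- try(file(path, "rb"), silent = TRUE)
  if (inherits(con, "try-error")) stop("invalid_audio: cannot open ", path)
  on.exit(close(con), add = TRUE)

  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("invalid_audio: not a RIFF file")
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("invalid_audio: not a WAVE file")

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(sz) == 0) break
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        fs           = readBin(con, "integer", 1, 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      )
      extra <- sz - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
      if (length(data_raw) < sz) stop("invalid_audio: truncated data chunk")
      break
    } else {
      skip <- readBin(con, "raw", sz + (sz %% 2L))
      if (length(skip) < sz) stop("invalid_audio: truncated file")
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("invalid_audio: missing fmt/data chunk")
  if (fmt$audio_format != 1L) stop("invalid_audio: only PCM supported")
  if (!fmt$bits %in% c(8L, 16L)) stop("invalid_audio: only 8/16-bit PCM supported")

  if (fmt$bits == 16L) {
    n <- length(data_raw) %/% 2L
    x <- readBin(data_raw, "integer", n, 2, signed = TRUE, endian = "little") / 32768
  } else {
    x <- (as.integer(data_raw) - 128) / 128
  }
  if (fmt$n_channels > 1L) {
    warning("multi-channel WAV downmixed to mono")
    nc <- fmt$n_channels
    nf <- length(x) %/% nc
    x <- rowMeans(matrix(x[seq_len(nf * nc)], ncol = nc, byrow = TRUE))
  }
  phonation(x, fmt$fs, meta = list(path = path, bits = fmt$bits))
}

#' Write a phonation as a 16-bit PCM RIFF WAV file
#'
#' Samples outside \[-1, 1\] are clipped; quantization is round-to-nearest.
#'
#' @param p A `phonation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phonation <- function(p, path) {
  stopifnot(inherits(p, "phonation"))
  x <- pmin(pmax(p$samples, -1), 32767 / 32768)
  pcm <- as.integer(round(x * 32768))
  pcm <- pmin(pmax(pcm, -32768L), 32767L)
  n_bytes <- length(pcm) * 2L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                       # PCM
  writeBin(1L, con, 2, endian = "little")                       # mono
  writeBin(as.integer(p$fs), con, 4, endian = "little")
  writeBin(as.integer(p$fs * 2L), con, 4, endian = "little")    # byte rate
  writeBin(2L, con, 2, endian = "little")                       # block align
  writeBin(16L, con, 2, endian = "little")                      # bits
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
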