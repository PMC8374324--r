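#' Read a mono WAV file
#'
#' Minimal RIFF/WAVE reader covering the formats heart-sound corpora use:
#' PCM 16-bit integer and IEEE float 32-bit, one or more channels (channels
#' are averaged to mono).  Integer samples are scaled to `[-1, 1)` by
#' dividing by 32768.
#'
#' @param path Path to a `.wav` file.
#' @return A list with `samples` (numeric vector) and `rate` (Hz).
#' @seealso [write_wav()], [pcg_recording()]
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw_fmt <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw_fmt[1:2], "integer", 1, 2, endian = "little"),
        channels     = readBin(raw_fmt[3:4], "integer", 1, 2, endian = "little"),
        rate         = readBin(raw_fmt[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw_fmt[15:16], "integer", 1, 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", sz / 2L, 2, signed = TRUE, endian = "little")
        samples <- x / 32768
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", sz / 4L, 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (format ", fmt$audio_format,
             ", ", fmt$bits, " bits); only PCM16 and float32 are supported")
      }
    } else {
      seek(con, sz + sz %% 2L, origin = "current")  # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (fmt$channels > 1L) {
    samples <- colMeans(matrix(samples, nrow = fmt$channels))
  }
  list(samples = as.numeric(samples), rate = fmt$rate)
}

#' Write a mono WAV file (PCM 16-bit)
#'
#' @param samples Numeric vector of amplitudes; values are clipped to
#'   `[-1, 1 - 1/32768]` before quantization.
#' @param rate Sample rate in Hz.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  stopifnot(is.numeric(samples), length(samples) >= 1, rate > 0)
  q <- as.integer(round(pmax(pmin(samples, 1 - 1 / 32768), -1) * 32768))
  n_bytes <- length(q) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(1L, con, 2, endian = "little")                 # PCM
  writeBin(1L, con, 2, endian = "little")                 # mono
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, 4, endian = "little")  # byte rate
  writeBin(2L, con, 2, endian = "little")                 # block align
  writeBin(16L, con, 2, endian = "little")                # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(q, con, 2, endian = "little")
  invisible(path)
}
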