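#' Write a waveform to a 16-bit PCM WAV file
#'
#' Minimal RIFF/WAVE writer: mono, 16-bit PCM, no dithering. Samples are
#' clipped to [-1, 1] and quantized to the nearest integer, so a round trip
#' through [read_wav()] reproduces the quantized samples bit-exactly.
#'
#' @param w a `waveform`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  s <- pmin(pmax(w$samples, -1), 1)
  pcm <- as.integer(round(s * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")           # fmt chunk size
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(w$rate), con, size = 4, endian = "little")
  writeBin(as.integer(w$rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")            # block align
  writeBin(16L, con, size = 2, endian = "little")           # bits per sample
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' Counterpart of [write_wav()]; reads mono 16-bit PCM RIFF/WAVE files.
#'
#' @param path file path.
#' @return a `waveform` with samples scaled back to [-1, 1].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  rate <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (fmt[1] != 1L) stop("only PCM WAV supported")
      if (fmt[2] != 1L) stop("only mono WAV supported")
      rate <- readBin(con, "integer", 1, size = 4, endian = "little")
      invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
      ba <- readBin(con, "integer", 2, size = 2, endian = "little")
      if (ba[2] != 16L) stop("only 16-bit WAV supported")
      skip <- size - 16L
      if (skip > 0) invisible(readBin(con, "raw", skip))
    } else if (identical(id, "data")) {
      pcm <- readBin(con, "integer", size %/% 2L, size = 2, endian = "little")
      return(new_waveform(pcm / 32767, rate))
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
}
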