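#' Write an audio buffer to a WAV file
#'
#' Writes a little-endian RIFF/WAVE file at the buffer's sample rate with the
#' buffer's channel count, either as 32-bit IEEE float (bit-exact round trip)
#' or 16-bit PCM (quantization error at most 2^-15).
#'
#' @param buffer an [audio_buffer()].
#' @param path output file path.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(buffer, path, format = c("float32", "pcm16")) {
  format <- match.arg(format)
  stopifnot(inherits(buffer, "audio_buffer"))
  nch <- buffer$n_channels
  sr <- as.integer(buffer$sample_rate)
  interleaved <- as.vector(t(buffer$samples))
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "float32") {
    audio_fmt <- 3L; bits <- 32L
    data_size <- length(interleaved) * 4L
  } else {
    audio_fmt <- 1L; bits <- 16L
    data_size <- length(interleaved) * 2L
  }
  block_align <- nch * bits / 8L
  byte_rate <- sr * block_align
  fact <- format == "float32"
  riff_size <- 4L + (8L + 16L) + (if (fact) 8L + 4L else 0L) + 8L + data_size
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(riff_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(audio_fmt, con, size = 2, endian = "little")
  writeBin(as.integer(nch), con, size = 2, endian = "little")
  writeBin(sr, con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  if (fact) {
    writeChar("fact", con, eos = NULL)
    writeBin(4L, con, size = 4, endian = "little")
    writeBin(as.integer(nrow(buffer$samples)), con, size = 4, endian = "little")
  }
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (format == "float32") {
    writeBin(interleaved, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmax(pmin(interleaved, 1), -1) * 32767)),
             con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' Parses RIFF chunks and supports 16-bit PCM and 32-bit float data.
#'
#' @param path WAV file path.
#' @return an [audio_buffer()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  readBin(con, "integer", size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        audio_fmt = readBin(con, "integer", size = 2, endian = "little"),
        nch = readBin(con, "integer", size = 2, endian = "little"),
        sr = readBin(con, "integer", size = 4, endian = "little"),
        byte_rate = readBin(con, "integer", size = 4, endian = "little"),
        block_align = readBin(con, "integer", size = 2, endian = "little"),
        bits = readBin(con, "integer", size = 2, endian = "little")
      )
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", n = size)
      break
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt/data")
  if (fmt$audio_fmt == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, "numeric", n = length(data_raw) / 4, size = 4,
                 endian = "little")
  } else if (fmt$audio_fmt == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, "integer", n = length(data_raw) / 2, size = 2,
                 endian = "little") / 32767
  } else {
    stop("unsupported WAV encoding")
  }
  audio_buffer(matrix(x, ncol = fmt$nch, byrow = TRUE), fmt$sr)
}
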