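# Minimal RIFF/WAVE reader and writer for uncompressed PCM.
#
# Recordings from the acquisition hardware are two-channel 80 kHz / 24-bit
# PCM WAV (channel 1 microphone, channel 2 camera reference pulses). No WAV
# package is assumed; the format is parsed directly with readBin/writeBin.
# Supported encodings: integer PCM 8/16/24/32 bit and IEEE float 32 bit.

#' Read an uncompressed WAV file
#'
#' @param path file path.
#' @return list with `samples` (numeric matrix, samples x channels, scaled to
#'   \[-1, 1\]), `sample_rate` (Hz) and `bit_depth`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  readBin(con, "integer", 1L, size = 4L, endian = "little")  # total size
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    tag <- rawToChar(id)
    if (identical(tag, "fmt ")) {
      body <- readBin(con, "raw", sz)
      fmt <- list(
        format = readBin(body[1:2], "integer", 1L, 2L, signed = FALSE,
                         endian = "little"),
        channels = readBin(body[3:4], "integer", 1L, 2L, signed = FALSE,
                           endian = "little"),
        sample_rate = readBin(body[5:8], "integer", 1L, 4L, endian = "little"),
        bits = readBin(body[15:16], "integer", 1L, 2L, signed = FALSE,
                       endian = "little")
      )
    } else if (identical(tag, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      readBin(con, "raw", sz + (sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("missing fmt/data chunk in WAV file: ", path, call. = FALSE)
  }
  bits <- fmt$bits
  ch <- fmt$channels
  if (fmt$format == 3L) {
    vals <- readBin(data_raw, "double", length(data_raw) %/% 4L, size = 4L,
                    endian = "little")
  } else if (bits == 8L) {
    v <- as.integer(data_raw)
    vals <- (v - 128) / 128
  } else if (bits == 16L) {
    vals <- readBin(data_raw, "integer", length(data_raw) %/% 2L, size = 2L,
                    endian = "little") / 32768
  } else if (bits == 24L) {
    n <- length(data_raw) %/% 3L
    m <- matrix(as.integer(data_raw), nrow = 3L)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    vals <- v / 2^23
  } else if (bits == 32L) {
    vals <- readBin(data_raw, "integer", length(data_raw) %/% 4L, size = 4L,
                    endian = "little") / 2^31
  } else {
    stop("unsupported WAV bit depth: ", bits, call. = FALSE)
  }
  samples <- matrix(vals, ncol = ch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate, bit_depth = bits)
}

#' Write an uncompressed PCM WAV file
#'
#' @param samples numeric vector or matrix (samples x channels) in \[-1, 1\].
#' @param path output path.
#' @param sample_rate sampling rate in Hz.
#' @param bit_depth 16, 24 or 32 (integer PCM).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 80000, bit_depth = 24L) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(bit_depth %in% c(16L, 24L, 32L))
  ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  interleaved <- pmax(-1, pmin(1, interleaved))
  bytes_per <- bit_depth %/% 8L
  block <- ch * bytes_per
  data_size <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")
  writeBin(as.integer(ch), con, size = 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4L, endian = "little")
  writeBin(as.integer(sample_rate * block), con, size = 4L, endian = "little")
  writeBin(as.integer(block), con, size = 2L, endian = "little")
  writeBin(as.integer(bit_depth), con, size = 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4L, endian = "little")
  if (bit_depth == 16L) {
    writeBin(as.integer(round(interleaved * 32767)), con, size = 2L,
             endian = "little")
  } else if (bit_depth == 32L) {
    writeBin(as.integer(round(interleaved * (2^31 - 1))), con, size = 4L,
             endian = "little")
  } else {
    v <- round(interleaved * (2^23 - 1))
    v <- ifelse(v < 0, v + 2^24, v)
    b1 <- as.raw(v %% 256)
    b2 <- as.raw((v %/% 256) %% 256)
    b3 <- as.raw((v %/% 65536) %% 256)
    writeBin(as.vector(rbind(b1, b2, b3)), con)
  }
  invisible(path)
}
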