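# WAV audio I/O. The target environment ships no R audio package, so a
# minimal RIFF/WAVE reader and writer are provided for the formats the
# data use: PCM16, PCM24 and IEEE float32, mono or interleaved
# multichannel. Integer PCM is rescaled to [-1, 1] by the full-scale
# negative value (e.g. int16 by 32768).

read_u32 <- function(con) readBin(con, "integer", 1, 4, signed = TRUE,
                                  endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1, 2, signed = FALSE,
                                  endian = "little")

#' Read one channel of a WAV file
#'
#' @param path path to a RIFF/WAVE file (PCM16, PCM24 or float32).
#' @param channel zero-based channel index (default 0, the convention for
#'   one file per participant).
#' @return a [uniform_series()] labelled `"raw_audio"` at the file's sample
#'   rate, values in `[-1, 1]` for integer PCM.
#' @export
read_audio <- function(path, channel = 0L) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4, useBytes = TRUE)
  if (!identical(magic, "RIFF"))
    stop(sprintf("'%s' is not a RIFF file", path), call. = FALSE)
  invisible(read_u32(con))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop(sprintf("'%s' is not a WAVE file", path), call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- read_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(audio_format = read_u16(con),
                  n_channels = read_u16(con),
                  sample_rate = read_u32(con))
      invisible(read_u32(con))            # byte rate
      invisible(read_u16(con))            # block align
      fmt$bits <- read_u16(con)
      extra <- size - 16L
      if (fmt$audio_format == 65534L && extra >= 12L) {  # WAVE_FORMAT_EXTENSIBLE
        invisible(read_u16(con))                         # cbSize
        invisible(read_u16(con))                         # valid bits
        invisible(read_u32(con))                         # channel mask
        fmt$audio_format <- read_u32(con)                # sub-format GUID head
        extra <- extra - 12L
      }
      if (extra > 0) invisible(readBin(con, "raw", extra))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2L == 1L) invisible(readBin(con, "raw", 1))
      if (!is.null(fmt)) break
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
  if (is.null(fmt) || is.null(data_raw))
    stop(sprintf("'%s': missing fmt or data chunk", path), call. = FALSE)
  channel <- as.integer(channel)
  if (channel < 0L || channel >= fmt$n_channels)
    stop(sprintf("channel %d out of range (file has %d channels)",
                 channel, fmt$n_channels), call. = FALSE)
  bytes_per <- fmt$bits %/% 8L
  n_total <- length(data_raw) %/% bytes_per
  if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", n_total, 2, signed = TRUE,
                 endian = "little") / 32768
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data_raw)
    b1 <- b[seq(1, 3 * n_total, 3)]
    b2 <- b[seq(2, 3 * n_total, 3)]
    b3 <- b[seq(3, 3 * n_total, 3)]
    v <- b1 + 256 * b2 + 65536 * b3
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
    x <- readBin(data_raw, "double", n_total, 4, endian = "little")
  } else {
    stop(sprintf("unsupported WAV encoding (format %d, %d bit)",
                 fmt$audio_format, fmt$bits), call. = FALSE)
  }
  ch <- x[seq(channel + 1L, length(x), by = fmt$n_channels)]
  uniform_series(ch, rate = fmt$sample_rate, label = "raw_audio")
}

#' Write a WAV file
#'
#' @param x numeric vector or matrix (samples x channels) in `[-1, 1]`.
#' @param path output path.
#' @param rate sample rate in Hz.
#' @param bits 16 (PCM16) or 32 (IEEE float32).
#' @return `path`, invisibly.
#' @export
write_audio <- function(x, path, rate, bits = 16L) {
  x <- as.matrix(x)
  n_channels <- ncol(x)
  inter <- as.numeric(t(x))
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  bytes_per <- bits %/% 8L
  data_size <- length(inter) * bytes_per
  writeChar("RIFF", con, eos = NULL); w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16L)
  w16(if (bits == 16L) 1L else 3L)
  w16(n_channels); w32(as.integer(rate))
  w32(as.integer(rate) * n_channels * bytes_per)
  w16(n_channels * bytes_per); w16(as.integer(bits))
  writeChar("data", con, eos = NULL); w32(data_size)
  if (bits == 16L) {
    v <- as.integer(pmax(pmin(round(inter * 32768), 32767), -32768))
    writeBin(v, con, 2, endian = "little")
  } else if (bits == 32L) {
    writeBin(inter, con, 4, endian = "little")
  } else stop("`bits` must be 16 or 32", call. = FALSE)
  invisible(path)
}
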