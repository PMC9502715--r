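# Minimal RIFF/WAVE reader and writer: PCM 16/24-bit and IEEE float32,
# any channel count.

#' Read a WAV file
#'
#' Supports PCM 16-bit, PCM 24-bit and IEEE float32, mono or multichannel.
#' Integer formats are scaled to [-1, 1).
#'
#' @param path file path.
#' @return list with `samples` (samples x channels matrix), `sample_rate`,
#'   `bit_depth` and `format` ("pcm" or "float").
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || !nzchar(id)) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, endian = "little", signed = FALSE),
        n_channels = readBin(raw[3:4], "integer", 1, 2, endian = "little", signed = FALSE),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little", signed = FALSE))
    } else if (identical(id, "data")) {
      data <- readBin(con, "raw", size)
      break
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
  if (is.null(fmt) || is.null(data)) stop("missing fmt or data chunk in ", path)
  nch <- fmt$n_channels
  if (fmt$audio_format == 3L || (fmt$audio_format == 65534L && fmt$bits == 32L)) {
    x <- readBin(data, "double", length(data) / 4, 4, endian = "little")
    format <- "float"
  } else if (fmt$audio_format == 1L && fmt$bits == 16L) {
    x <- readBin(data, "integer", length(data) / 2, 2, endian = "little") / 32768
    format <- "pcm"
  } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
    b <- as.integer(data)
    n <- length(b) %/% 3
    v <- b[seq(1, 3 * n, 3)] + 256 * b[seq(2, 3 * n, 3)] + 65536 * b[seq(3, 3 * n, 3)]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
    format <- "pcm"
  } else {
    stop(sprintf("unsupported WAV format (code %d, %d bits)", fmt$audio_format, fmt$bits))
  }
  samples <- matrix(x, ncol = nch, byrow = TRUE)
  list(samples = samples, sample_rate = fmt$sample_rate, bit_depth = fmt$bits,
       format = format)
}

#' Write a WAV file
#'
#' @param samples numeric vector (mono), samples x channels matrix, or an
#'   [mc_signal()] (written channels-as-columns).
#' @param path output path.
#' @param sample_rate sampling rate in Hz; taken from an `mc_signal` input
#'   when omitted.
#' @param bit_depth 16, 24 (PCM) or 32 (IEEE float).
#' @return the path, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = NULL, bit_depth = 32) {
  if (inherits(samples, "mc_signal")) {
    if (is.null(sample_rate)) sample_rate <- samples$sample_rate
    samples <- t(samples$samples)
  }
  if (is.null(sample_rate)) stop("sample_rate is required")
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  if (!bit_depth %in% c(16, 24, 32)) stop("bit_depth must be 16, 24 or 32")
  nch <- ncol(samples)
  inter <- as.numeric(t(samples))  # interleave channels
  bytes_per <- bit_depth / 8
  data_size <- length(inter) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(if (bit_depth == 32) 3L else 1L, nch), con, 2, endian = "little")
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * nch * bytes_per), con, 4, endian = "little")
  writeBin(c(as.integer(nch * bytes_per), as.integer(bit_depth)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 32) {
    writeBin(inter, con, 4, endian = "little")
  } else if (bit_depth == 16) {
    v <- as.integer(pmax(pmin(round(inter * 32768), 32767), -32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    v <- round(pmax(pmin(inter, 1 - 1 / 8388608), -1) * 8388608)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256))
    writeBin(b, con)
  }
  invisible(path)
}
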