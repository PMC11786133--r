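# Minimal RIFF/WAVE reader and writer for PCM16, PCM24 and IEEE float32,
# mono or stereo. Chunk-based: unknown chunks are skipped; only `fmt ` and
# `data` are interpreted. Samples are exchanged as a channels-in-columns
# numeric matrix scaled to [-1, 1].

WAVE_FORMAT_PCM <- 1L
WAVE_FORMAT_IEEE_FLOAT <- 3L
WAVE_FORMAT_EXTENSIBLE <- 65534L

#' Construct an audio signal
#'
#' The in-memory audio container: a samples-by-channels numeric matrix with
#' amplitudes in `[-1, 1]` plus a sample rate. Mono vectors are promoted to
#' one-column matrices.
#'
#' @param samples Numeric vector (mono) or matrix with one column per channel.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return An object of class `audio_signal` with fields `samples`,
#'   `sample_rate_hz`, `n_channels`.
#' @export
audio_signal <- function(samples, sample_rate_hz) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric vector or matrix.", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("Audio samples must all be finite.", call. = FALSE)
  }
  if (ncol(samples) > 2) {
    stop("Only mono or stereo audio is supported (got ", ncol(samples),
         " channels).", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1 ||
      sample_rate_hz <= 0) {
    stop("`sample_rate_hz` must be a single positive number.", call. = FALSE)
  }
  structure(
    list(samples = samples,
         sample_rate_hz = as.numeric(sample_rate_hz),
         n_channels = ncol(samples)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal: %d samples x %d channel(s), %g Hz (%.3f s)\n",
              nrow(x$samples), x$n_channels, x$sample_rate_hz,
              nrow(x$samples) / x$sample_rate_hz))
  invisible(x)
}

read_u32 <- function(con) readBin(con, "integer", 1, 4, signed = TRUE,
                                  endian = "little")
read_u16 <- function(con) readBin(con, "integer", 1, 2, signed = FALSE,
                                  endian = "little")

#' Read a WAV file
#'
#' Supports PCM16, PCM24 and IEEE float32 encodings (also the EXTENSIBLE
#' wrapper around them), mono or stereo, any sample rate. Integer samples are
#' scaled by the full-scale value of their bit depth.
#'
#' @param path Path to a `.wav` file.
#' @return An [audio_signal()]; its `bit_type` attribute records the source
#'   encoding (`"pcm16"`, `"pcm24"` or `"float32"`).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    stop("Not a RIFF file: ", path, call. = FALSE)
  }
  invisible(read_u32(con))  # overall size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    stop("Not a WAVE file: ", path, call. = FALSE)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- read_u32(con)
    if (identical(id, "fmt ")) {
      fmt <- list(
        format = read_u16(con),
        channels = read_u16(con),
        sample_rate = read_u32(con),
        byte_rate = read_u32(con),
        block_align = read_u16(con),
        bits = read_u16(con)
      )
      remaining <- size - 16
      if (fmt$format == WAVE_FORMAT_EXTENSIBLE && remaining >= 8) {
        cb <- read_u16(con)
        invisible(read_u16(con))            # valid bits
        invisible(read_u32(con))            # channel mask
        sub <- readBin(con, "raw", 16)      # subformat GUID; first 2 bytes = code
        fmt$format <- as.integer(sub[1]) + 256L * as.integer(sub[2])
        remaining <- remaining - 2 - cb
      }
      if (remaining > 0) invisible(readBin(con, "raw", remaining))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
      if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # pad byte
      if (!is.null(fmt)) break
    } else {
      invisible(readBin(con, "raw", size + size %% 2))
    }
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("Malformed WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  if (!fmt$channels %in% 1:2) {
    stop("Unsupported channel count: ", fmt$channels, call. = FALSE)
  }
  decode <- function(raw) {
    if (fmt$format == WAVE_FORMAT_IEEE_FLOAT && fmt$bits == 32) {
      readBin(raw, "double", length(raw) / 4, size = 4, endian = "little")
    } else if (fmt$format == WAVE_FORMAT_PCM && fmt$bits == 16) {
      readBin(raw, "integer", length(raw) / 2, size = 2, signed = TRUE,
              endian = "little") / 32768
    } else if (fmt$format == WAVE_FORMAT_PCM && fmt$bits == 24) {
      b <- as.integer(raw)
      n <- length(b) / 3
      v <- b[seq(1, by = 3, length.out = n)] +
        256 * b[seq(2, by = 3, length.out = n)] +
        65536 * b[seq(3, by = 3, length.out = n)]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else {
      stop(sprintf("Unsupported WAV encoding (format %d, %d-bit).",
                   fmt$format, fmt$bits), call. = FALSE)
    }
  }
  flat <- decode(data_raw)
  mat <- matrix(flat, ncol = fmt$channels, byrow = TRUE)
  sig <- audio_signal(mat, fmt$sample_rate)
  attr(sig, "bit_type") <- switch(
    paste(fmt$format, fmt$bits),
    "1 16" = "pcm16", "1 24" = "pcm24", "3 32" = "float32")
  sig
}

#' Write a WAV file
#'
#' @param signal An [audio_signal()]. Samples outside `[-1, 1]` are clipped
#'   with a warning for integer encodings.
#' @param path Output path.
#' @param bit_type `"pcm16"`, `"pcm24"` or `"float32"`.
#' @return `path`, invisibly.
#' @rdname read_wav
#' @export
write_wav <- function(signal, path, bit_type = c("pcm16", "pcm24", "float32")) {
  stopifnot(inherits(signal, "audio_signal"))
  bit_type <- match.arg(bit_type)
  x <- t(signal$samples)             # interleave: channels fastest
  flat <- as.vector(x)
  n_ch <- signal$n_channels
  if (bit_type != "float32" && any(abs(flat) > 1)) {
    warning("Samples outside [-1, 1] clipped on write.")
    flat <- pmin(1, pmax(-1, flat))
  }
  bits <- switch(bit_type, pcm16 = 16L, pcm24 = 24L, float32 = 32L)
  fmt_code <- if (bit_type == "float32") WAVE_FORMAT_IEEE_FLOAT else
    WAVE_FORMAT_PCM
  bytes_per <- bits / 8L
  data_size <- length(flat) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(v) writeBin(as.integer(v), con, 4, endian = "little")
  w16 <- function(v) writeBin(as.integer(v), con, 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36 + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16)
  w16(fmt_code)
  w16(n_ch)
  w32(signal$sample_rate_hz)
  w32(signal$sample_rate_hz * n_ch * bytes_per)
  w16(n_ch * bytes_per)
  w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (bit_type == "float32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else if (bit_type == "pcm16") {
    v <- as.integer(round(flat * 32767))
    writeBin(v, con, size = 2, endian = "little")
  } else {
    v <- round(flat * 8388607)
    v <- ifelse(v < 0, v + 16777216, v)
    b <- integer(3 * length(v))
    b[seq(1, by = 3, length.out = length(v))] <- v %% 256
    b[seq(2, by = 3, length.out = length(v))] <- (v %/% 256) %% 256
    b[seq(3, by = 3, length.out = length(v))] <- (v %/% 65536) %% 256
    writeBin(as.raw(b), con)
  }
  invisible(path)
}
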