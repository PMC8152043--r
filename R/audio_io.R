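#' Mono audio stream
#'
#' Container for a mono, 16-bit PCM audio signal as produced by the texture
#' sensor front end: a condenser microphone sampled by a microcontroller ADC.
#' Samples are raw signed ADC counts; `scale_mv_per_count` converts counts to
#' millivolts so that spectral magnitudes can be compared against the
#' energy-gate threshold (see [transfer_params()]).
#'
#' The default count-to-millivolt scale maps a full-scale sample (32768
#' counts) to a 3.3 V ADC reference, i.e. `3300/32768` mV per count. The
#' hardware calibration is not uniquely determined by the system description,
#' so the scale is an explicit, documented parameter rather than a constant.
#'
#' @param samples Numeric vector of integer-valued samples in
#'   `[-32768, 32767]`.
#' @param rate_hz Sampling rate in Hz (default 6000, the rate used by the
#'   sensor front end; friction sound content lies below 3 kHz).
#' @param scale_mv_per_count Millivolts per ADC count (default `3300/32768`).
#' @return An object of class `"audio_stream"`: a list with elements
#'   `samples` (integer vector), `rate_hz` and `scale_mv_per_count`.
#' @examples
#' s <- audio_stream(round(1000 * sin(2 * pi * 440 * (0:5999) / 6000)))
#' s
#' @seealso [read_wav()], [write_wav()], [frame_stream()]
#' @export
audio_stream <- function(samples, rate_hz = 6000,
                         scale_mv_per_count = 3300 / 32768) {
  samples <- as.numeric(samples)
  if (length(samples) && any(!is.finite(samples))) {
    stop("samples must be finite")
  }
  if (length(samples) && any(samples < -32768 | samples > 32767)) {
    stop("samples outside the signed 16-bit range [-32768, 32767]")
  }
  if (length(samples) && any(samples != round(samples))) {
    stop("samples must be integer ADC counts")
  }
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || !is.finite(rate_hz) ||
      rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  if (!is.numeric(scale_mv_per_count) || length(scale_mv_per_count) != 1L ||
      scale_mv_per_count <= 0) {
    stop("scale_mv_per_count must be a single positive number")
  }
  structure(
    list(samples = as.integer(samples), rate_hz = rate_hz,
         scale_mv_per_count = scale_mv_per_count),
    class = "audio_stream"
  )
}

#' @export
print.audio_stream <- function(x, ...) {
  cat(sprintf("<audio_stream> %d samples @ %g Hz (%.3f s), %.4f mV/count\n",
              length(x$samples), x$rate_hz, length(x$samples) / x$rate_hz,
              x$scale_mv_per_count))
  invisible(x)
}

#' @export
length.audio_stream <- function(x) length(x$samples)

# --- WAV I/O ----------------------------------------------------------------
# Minimal RIFF/PCM reader-writer fixed to the one dialect the pipeline uses:
# mono, 16-bit, little-endian PCM. Anything else is rejected, not converted.

u32le <- function(raw4) sum(as.numeric(raw4) * 256^(0:3))
u16le <- function(raw2) sum(as.numeric(raw2) * 256^(0:1))

#' Read a mono 16-bit PCM WAV file
#'
#' Reads a RIFF/WAVE file containing uncompressed mono 16-bit PCM audio and
#' returns it as an [audio_stream()]. Multi-channel, non-16-bit or compressed
#' files are rejected with an error naming the offending property; the
#' pipeline treats its input format as a fixed contract rather than guessing
#' conversions.
#'
#' @param path Path to a WAV file.
#' @param scale_mv_per_count Count-to-millivolt scale to attach to the
#'   returned stream (not stored in WAV; default as in [audio_stream()]).
#' @return An `"audio_stream"` whose `rate_hz` comes from the file header.
#' @export
read_wav <- function(path, scale_mv_per_count = 3300 / 32768) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 44 || rawToChar(raw[1:4]) != "RIFF" ||
      rawToChar(raw[9:12]) != "WAVE") {
    stop("not a RIFF/WAVE file: ", path)
  }
  pos <- 13L
  fmt <- NULL
  data_raw <- NULL
  while (pos + 8L <= length(raw) + 1L) {
    id <- rawToChar(raw[pos:(pos + 3L)])
    size <- u32le(raw[(pos + 4L):(pos + 7L)])
    body_start <- pos + 8L
    body_end <- body_start + size - 1L
    if (body_end > length(raw)) body_end <- length(raw)
    if (id == "fmt ") {
      body <- raw[body_start:body_end]
      fmt <- list(
        audio_format = u16le(body[1:2]),
        channels     = u16le(body[3:4]),
        sample_rate  = u32le(body[5:8]),
        bits         = u16le(body[15:16])
      )
    } else if (id == "data") {
      data_raw <- raw[body_start:body_end]
    }
    # chunks are word-aligned: odd sizes carry one pad byte
    pos <- body_start + size + (size %% 2)
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw)) stop("WAV file has no data chunk: ", path)
  if (fmt$audio_format != 1) {
    stop("unsupported WAV encoding (audio format ", fmt$audio_format,
         "): only uncompressed PCM is supported")
  }
  if (fmt$channels != 1) {
    stop("unsupported channel count (", fmt$channels,
         "): only mono is supported")
  }
  if (fmt$bits != 16) {
    stop("unsupported bit depth (", fmt$bits,
         "-bit): only 16-bit is supported")
  }
  samples <- readBin(data_raw, "integer", n = length(data_raw) %/% 2L,
                     size = 2L, signed = TRUE, endian = "little")
  audio_stream(samples, rate_hz = fmt$sample_rate,
               scale_mv_per_count = scale_mv_per_count)
}

#' Write an audio stream as mono 16-bit PCM WAV
#'
#' @param stream An [audio_stream()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(stream, path) {
  stopifnot(inherits(stream, "audio_stream"))
  n <- length(stream$samples)
  data_bytes <- 2L * n
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")            # PCM
  writeBin(1L, con, size = 2L, endian = "little")            # mono
  writeBin(as.integer(round(stream$rate_hz)), con, size = 4L,
           endian = "little")
  writeBin(as.integer(round(stream$rate_hz)) * 2L, con, size = 4L,
           endian = "little")                                # byte rate
  writeBin(2L, con, size = 2L, endian = "little")            # block align
  writeBin(16L, con, size = 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4L, endian = "little")
  writeBin(stream$samples, con, size = 2L, endian = "little")
  invisible(path)
}

#' Slice a stream into overlapping analysis windows
#'
#' Returns the sliding windows used by the spectral stage: windows of
#' `window` samples advancing by `hop` samples, as the columns of a matrix.
#' The number of windows is `floor((N - window)/hop) + 1`; a stream shorter
#' than one window yields a zero-column matrix (silent stubs flow through
#' the pipeline rather than erroring).
#'
#' @param stream An [audio_stream()] or a plain numeric vector.
#' @param window Window length in samples (default 2048).
#' @param hop Hop (update stride) in samples (default 128).
#' @return Numeric matrix with `window` rows, one column per window.
#' @examples
#' frame_stream(audio_stream(integer(6000)), 2048, 128)  # 31 windows
#' @export
frame_stream <- function(stream, window = 2048, hop = 128) {
  if (!is.numeric(window) || length(window) != 1L || window < 1 ||
      !is.numeric(hop) || length(hop) != 1L || hop < 1 || hop > window) {
    stop("need window >= hop >= 1")
  }
  x <- if (inherits(stream, "audio_stream")) as.numeric(stream$samples)
       else as.numeric(stream)
  n <- length(x)
  window <- as.integer(window); hop <- as.integer(hop)
  if (n < window) return(matrix(numeric(0), nrow = window, ncol = 0))
  nwin <- (n - window) %/% hop + 1L
  idx <- rep(seq_len(window), nwin) +
    rep((seq_len(nwin) - 1L) * hop, each = window)
  matrix(x[idx], nrow = window, ncol = nwin)
}

#' Dump raw samples to CSV
#'
#' Writes one sample per row with columns `t_s` (time of the sample in
#' seconds) and `amplitude` (ADC counts).
#'
#' @param stream An [audio_stream()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples_csv <- function(stream, path) {
  stopifnot(inherits(stream, "audio_stream"))
  df <- data.frame(
    t_s = (seq_along(stream$samples) - 1) / stream$rate_hz,
    amplitude = stream$samples
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
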