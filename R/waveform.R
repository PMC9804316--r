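#' Construct a waveform object
#'
#' A waveform is the package's universal signal currency: a mono sequence of
#' dimensionless amplitude samples (peak magnitude at most 1) together with
#' its sample rate.
#'
#' @param samples Numeric vector of amplitude samples; `max(abs(samples))`
#'   must not exceed 1 (a tiny numerical overshoot up to 1 + 1e-9 is clipped).
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"waveform"`: a list with elements `samples`
#'   and `sample_rate`.
#' @examples
#' w <- waveform(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 44100)), 44100)
#' duration(w)
#' @export
waveform <- function(samples, sample_rate) {
  if (!is.numeric(samples)) stop("samples must be numeric")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar (Hz)")
  samples <- as.numeric(samples)
  peak <- if (length(samples)) max(abs(samples)) else 0
  if (peak > 1 + 1e-9) stop("waveform peak amplitude exceeds 1")
  if (peak > 1) samples <- samples / peak
  structure(list(samples = samples, sample_rate = sample_rate),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.4g s), peak %.3g\n",
              length(x$samples), x$sample_rate,
              length(x$samples) / x$sample_rate,
              if (length(x$samples)) max(abs(x$samples)) else 0))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A [waveform()].
#' @return Duration in seconds.
#' @export
duration <- function(w) {
  stopifnot(inherits(w, "waveform"))
  length(w$samples) / w$sample_rate
}

#' Write a waveform to a WAV file
#'
#' Writes a mono RIFF/WAVE file, either 16-bit PCM (`"pcm16"`) or 32-bit IEEE
#' float (`"float32"`). PCM16 quantizes with rounding, so a round-trip agrees
#' with the original samples to within one quantization step (2^-15).
#'
#' @param w A [waveform()].
#' @param path Output file path.
#' @param encoding `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @seealso [read_wav()]
#' @export
write_wav <- function(w, path, encoding = c("pcm16", "float32")) {
  stopifnot(inherits(w, "waveform"))
  encoding <- match.arg(encoding)
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(w$samples)
  fs <- as.integer(round(w$sample_rate))
  if (encoding == "pcm16") {
    fmt_code <- 1L; bits <- 16L; bytes_per <- 2L
  } else {
    fmt_code <- 3L; bits <- 32L; bytes_per <- 4L
  }
  data_bytes <- n * bytes_per
  block_align <- bytes_per            # mono
  byte_rate <- fs * block_align
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_code, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # channels
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(byte_rate), con, size = 4, endian = "little")
  writeBin(as.integer(block_align), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (encoding == "pcm16") {
    x <- pmax(pmin(w$samples, 1), -1)
    q <- as.integer(round(x * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(w$samples, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports 16-bit PCM and 32-bit IEEE float, mono or multichannel (channels
#' are averaged to mono on read). Anything that is not a RIFF/WAVE stream, or
#' uses another sample encoding, is rejected.
#'
#' @param path WAV file path.
#' @return A [waveform()].
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file")
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file")
  fmt_code <- NA_integer_; n_chan <- NA_integer_; fs <- NA_integer_
  bits <- NA_integer_; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt_code <- readBin(con, integer(), size = 2, endian = "little")
      n_chan <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16) readBin(con, raw(), n = sz - 16L)
    } else if (identical(id, "data")) {
      if (is.na(fmt_code)) stop("malformed WAV: data chunk before fmt chunk")
      if (fmt_code == 1L && bits == 16L) {
        raw_vals <- readBin(con, integer(), n = sz / 2L, size = 2,
                            endian = "little", signed = TRUE)
        samples <- raw_vals / 32767
      } else if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = sz / 4L, size = 4,
                           endian = "little")
      } else {
        stop(sprintf("unsupported WAV encoding (format %d, %d-bit)",
                     fmt_code, bits))
      }
    } else {
      readBin(con, raw(), n = sz)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop("no data chunk found in WAV file")
  if (n_chan > 1L) {
    samples <- rowMeans(matrix(samples, ncol = n_chan, byrow = TRUE))
  }
  waveform(pmax(pmin(samples, 1), -1), fs)
}
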