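#' @title Peripheral auditory front end
#' @name periphery
#' @description
#' Gammatone filterbank (Slaney-style 4th-order all-pole design, ERB
#' bandwidths) and a Meddis hair-cell transduction stage. Together they turn a
#' waveform into the multichannel drive signal `x(f, t)` that the summary
#' autocorrelation integrates over.
NULL

#' Equivalent rectangular bandwidth (Glasberg & Moore)
#'
#' `ERB(cf) = 24.7 * (4.37 * cf / 1000 + 1)` Hz.
#'
#' @param cf Centre frequency in Hz.
#' @return Bandwidth in Hz.
#' @export
erb <- function(cf) 24.7 * (4.37 * cf / 1000 + 1)

#' Design a log-spaced gammatone filterbank
#'
#' Centre frequencies form a geometric sequence from `cf_low` to `cf_high`
#' inclusive (constant CF ratio between adjacent channels). Each channel is a
#' 4th-order gammatone with bandwidth `1.019 * ERB(cf)`. The default bank is
#' 50 channels spanning 300-3000 Hz.
#'
#' @param n_channels Number of channels (>= 2).
#' @param cf_low,cf_high Lowest/highest centre frequency in Hz;
#'   `cf_high` must be below Nyquist.
#' @param sample_rate Sampling rate in Hz.
#' @return An object of class `"filterbank_spec"` with elements `cfs`,
#'   `n_channels`, `cf_low`, `cf_high`, `sample_rate` and the per-channel
#'   second-order-section coefficients.
#' @examples
#' fb <- design_filterbank()
#' range(fb$cfs)
#' @export
design_filterbank <- function(n_channels = 50, cf_low = 300, cf_high = 3000,
                              sample_rate = 44100) {
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (cf_low >= cf_high) stop("cf_low must be below cf_high")
  if (cf_high >= sample_rate / 2) stop("cf_high must be below Nyquist")
  cfs <- exp(seq(log(cf_low), log(cf_high), length.out = n_channels))
  coefs <- lapply(cfs, gammatone_coefs, sample_rate = sample_rate)
  structure(list(n_channels = as.integer(n_channels), cf_low = cf_low,
                 cf_high = cf_high, sample_rate = sample_rate,
                 cfs = cfs, coefs = coefs),
            class = "filterbank_spec")
}

# Slaney (1993) 4th-order all-pole gammatone as a cascade of four biquads
# sharing one denominator; returns numerators (scaled by overall gain),
# denominator, for use with signal::filter.
gammatone_coefs <- function(cf, sample_rate) {
  T <- 1 / sample_rate
  B <- 1.019 * 2 * pi * erb(cf)
  ct <- cos(2 * cf * pi * T)
  st <- sin(2 * cf * pi * T)
  eB <- exp(B * T)
  A0 <- T; A2 <- 0
  B0 <- 1; B1 <- -2 * ct / eB; B2 <- exp(-2 * B * T)
  sq_p <- sqrt(3 + 2^1.5)
  sq_m <- sqrt(3 - 2^1.5)
  A11 <- -(2 * T * ct / eB + 2 * sq_p * T * st / eB) / 2
  A12 <- -(2 * T * ct / eB - 2 * sq_p * T * st / eB) / 2
  A13 <- -(2 * T * ct / eB + 2 * sq_m * T * st / eB) / 2
  A14 <- -(2 * T * ct / eB - 2 * sq_m * T * st / eB) / 2
  z <- exp(4i * cf * pi * T)
  w <- exp(-(B * T) + 2i * cf * pi * T)
  gain <- abs(
    (-2 * z * T + 2 * w * T * (ct - sq_m * st)) *
    (-2 * z * T + 2 * w * T * (ct + sq_m * st)) *
    (-2 * z * T + 2 * w * T * (ct - sq_p * st)) *
    (-2 * z * T + 2 * w * T * (ct + sq_p * st)) /
    (-2 / exp(2 * B * T) - 2 * z + 2 * (1 + z) / eB)^4)
  list(b1 = c(A0 / gain, A11 / gain, A2 / gain),
       b2 = c(A0, A12, A2), b3 = c(A0, A13, A2), b4 = c(A0, A14, A2),
       a = c(B0, B1, B2))
}

new_multichannel <- function(data, cfs, sample_rate, stage) {
  structure(list(data = data, cfs = cfs, sample_rate = sample_rate,
                 stage = stage),
            class = "multichannel")
}

#' @export
print.multichannel <- function(x, ...) {
  cat(sprintf("<multichannel:%s> %d channels x %d samples @ %g Hz, CFs %.0f-%.0f Hz\n",
              x$stage, nrow(x$data), ncol(x$data), x$sample_rate,
              min(x$cfs), max(x$cfs)))
  invisible(x)
}

#' Apply a gammatone filterbank to a waveform
#'
#' Filters the waveform through each channel's 4th-order gammatone. The
#' operation is linear: scaling the input scales every channel's output.
#'
#' @param w A [waveform()].
#' @param fb A [design_filterbank()] spec with matching sample rate.
#' @return A `"multichannel"` object (`stage = "filterbank"`): a channels x
#'   time matrix plus the channel CFs.
#' @examples
#' fb <- design_filterbank(12, 300, 3000, 16000)
#' mcs <- apply_filterbank(make_pure_tone(500, 0.05, 16000), fb)
#' @export
apply_filterbank <- function(w, fb) {
  stopifnot(inherits(w, "waveform"), inherits(fb, "filterbank_spec"))
  if (length(w$samples) == 0L) stop("empty waveform")
  if (w$sample_rate != fb$sample_rate) stop("sample rates do not match")
  n <- length(w$samples)
  out <- matrix(0, nrow = fb$n_channels, ncol = n)
  for (k in seq_len(fb$n_channels)) {
    cf <- fb$coefs[[k]]
    y <- signal::filter(cf$b1, cf$a, w$samples)
    y <- signal::filter(cf$b2, cf$a, y)
    y <- signal::filter(cf$b3, cf$a, y)
    y <- signal::filter(cf$b4, cf$a, y)
    out[k, ] <- as.numeric(y)
  }
  new_multichannel(out, fb$cfs, fb$sample_rate, "filterbank")
}

#' Meddis inner-hair-cell transduction
#'
#' Applies the Meddis (1986/1988) transmitter-reservoir hair-cell model to
#' each filterbank channel, using the constants of Slaney's Auditory Toolbox
#' coding of the model (A = 5, B = 300, g = 2000, y = 5.05, l = 2500,
#' r = 6580, x = 66.31, h = 50000, M = 1). Reservoirs start at their silence
#' steady state, so silence in gives a constant spontaneous level out. The
#' output is a nonnegative firing-probability-like signal that preserves
#' phase-locked modulation at the channel CF.
#'
#' The model operates on basilar-membrane displacement in its own units; the
#' peak-1 stimuli of this package are mapped into its dynamic range by a
#' single global `gain` (default 100) used throughout all analyses.
#'
#' @param mcs A `"multichannel"` object at stage `"filterbank"`.
#' @param gain Linear input gain applied before transduction.
#' @return A `"multichannel"` object at stage `"haircell"` (all values >= 0).
#' @export
ihc_transduce <- function(mcs, gain = 100) {
  stopifnot(inherits(mcs, "multichannel"))
  if (mcs$stage != "filterbank")
    stop("input must be at the filterbank stage (not already transduced)")
  A <- 5; B <- 300; g <- 2000; y <- 5.05
  l <- 2500; r <- 6580; x <- 66.31; h <- 50000; M <- 1
  dt <- 1 / mcs$sample_rate
  gdt <- g * dt; ydt <- y * dt; ldt <- l * dt; rdt <- r * dt; xdt <- x * dt
  # silence steady state
  kt0 <- g * A / (A + B)
  spont <- M * y * kt0 / (l * kt0 + y * (l + r))
  nch <- nrow(mcs$data); n <- ncol(mcs$data)
  q <- rep(spont * (l + r) / kt0, nch)
  w <- rep(spont * r / x, nch)
  c_ <- rep(spont, nch)
  out <- matrix(0, nch, n)
  s <- mcs$data * gain
  for (i in seq_len(n)) {
    limited <- pmax(s[, i] + A, 0)
    kt <- gdt * limited / (limited + B)
    replenish <- pmax(ydt * (M - q), 0)
    eject <- kt * q
    loss <- ldt * c_
    reuptake <- rdt * c_
    reprocess <- xdt * w
    q <- q + replenish - eject + reprocess
    c_ <- c_ + eject - loss - reuptake
    w <- w + reuptake - reprocess
    out[, i] <- c_
  }
  out <- out * h
  out[out < 0] <- 0
  new_multichannel(out, mcs$cfs, mcs$sample_rate, "haircell")
}

#' Element-wise power nonlinearity
#'
#' Raises every sample to the given exponent (sign preserved for the cubic),
#' enhancing the ridges of the filtered signal. Used to probe how strongly a
#' weak periodicity cue can be forced into the autocorrelation output.
#'
#' @param mcs A `"multichannel"` object.
#' @param exponent 2 (square) or 3 (cubic).
#' @return A `"multichannel"` object at stage `"nonlinear"`.
#' @export
apply_nonlinearity <- function(mcs, exponent) {
  stopifnot(inherits(mcs, "multichannel"))
  if (!exponent %in% c(2, 3)) stop("exponent must be 2 or 3")
  d <- if (exponent == 2) mcs$data^2 else sign(mcs$data) * abs(mcs$data)^3
  new_multichannel(d, mcs$cfs, mcs$sample_rate, "nonlinear")
}
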