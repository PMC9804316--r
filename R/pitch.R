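#' @title Summary autocorrelation pitch extraction
#' @name pitch
#' @description
#' The pitch stage integrates, across the filterbank channels, an
#' exponentially weighted running autocorrelation of each channel's hair-cell
#' drive signal:
#'
#' \deqn{R_t(\tau) = \int_{f_l}^{f_u} \int_{T=0}^{\infty}
#'   x(f, t-T)\, x(f, t-\tau-T)\, e^{-T/0.005}\, dT\, df}
#'
#' where `x` is the per-channel waveform, `T` is time into the past relative
#' to the evaluation time `t`, the exponential memory has a 5-ms time constant
#' and `tau` is the autocorrelation lag. The summary autocorrelation (SACF) is
#' normalized by its lag-0 value; its highest non-zero-lag peak is the model's
#' pitch estimate (frequency = 1/lag). The absence of such a peak is an
#' explicit result, not an error.
NULL

#' Compute the summary autocorrelation function
#'
#' Discretizes the exponentially weighted, channel-integrated autocorrelation
#' at one evaluation time. The memory integral over `T` is truncated at
#' `5 * decay_tau` (where the kernel has fallen below `exp(-5)`); signal
#' before sample 1 is treated as silence. The result is normalized by its
#' lag-0 value.
#'
#' Two numerical choices make the summary interpretable as a periodicity
#' statistic. First, the hair-cell drive carries a large positive DC component
#' (spontaneous plus sustained rate) that holds no periodicity information but
#' would dominate the normalized autocorrelation, flattening it toward 1 at
#' every lag; each channel's exponentially weighted mean over the memory
#' window is subtracted before correlating. Second, each channel's
#' autocorrelation pattern is normalized before the patterns are integrated
#' across channels (`per_channel_norm = TRUE`, the default): the weighted
#' correlation at each lag is divided by the geometric mean of the two
#' segments' weighted powers, making every channel's pattern a bona fide
#' correlation coefficient in `[-1, 1]`. A periodic stimulus drives every
#' responding channel at the stimulus period, so the normalized patterns add
#' coherently into a large non-zero-lag peak; a brief FM sweep instead leaves
#' each filter ringing at its own centre frequency, the patterns peak at fifty
#' different periods and their sum retains no common peak — which is what
#' makes the model's "no pitch estimate for FM pulses" outcome observable.
#' Channels whose centered power falls below `1e-9` of the strongest channel
#' are excluded from the integration (they contain no modulation to
#' normalize). With `per_channel_norm = FALSE` the channel patterns are summed
#' raw and the sum divided by its lag-0 value, the literal reading of the
#' integral. A signal with (numerically) no modulation at all yields the
#' degenerate SACF that is 1 at lag 0 and 0 elsewhere.
#'
#' @param mcs A `"multichannel"` object at stage `"haircell"` or
#'   `"nonlinear"`.
#' @param eval_time Evaluation time `t` in seconds (within the signal).
#' @param lag_max Largest lag in seconds (default 0.0125, covering pitches
#'   down to 80 Hz); must be positive and below `eval_time`.
#' @param decay_tau Memory time constant in seconds (default 0.005).
#' @param channel_range Optional `c(f_l, f_u)` in Hz restricting which
#'   channels are integrated (default: all).
#' @param per_channel_norm Normalize each channel's autocorrelation pattern to
#'   a correlation coefficient before integrating across channels (default
#'   `TRUE`; see Details).
#' @return An object of class `"sacf"`: `lags` (seconds, starting at 0),
#'   `amplitude` (normalized, amplitude at lag 0 equals 1), `eval_time`,
#'   `decay_tau`, `channel_range`.
#' @examples
#' fb <- design_filterbank(10, 300, 3000, 16000)
#' hc <- ihc_transduce(apply_filterbank(make_pure_tone(500, 0.1, 16000), fb))
#' s <- sacf(hc, eval_time = 0.1)
#' @export
sacf <- function(mcs, eval_time, lag_max = 0.0125, decay_tau = 0.005,
                 channel_range = NULL, per_channel_norm = TRUE) {
  stopifnot(inherits(mcs, "multichannel"))
  if (!mcs$stage %in% c("haircell", "nonlinear"))
    stop("SACF input must be hair-cell or nonlinear stage output")
  fs <- mcs$sample_rate
  n <- ncol(mcs$data)
  if (lag_max <= 0) stop("lag_max must be positive")
  if (eval_time > n / fs + 1e-12) stop("eval_time beyond signal end")
  if (lag_max >= eval_time) stop("lag_max must be below eval_time")
  keep <- channel_mask(mcs, channel_range)
  it <- min(max(1L, round(eval_time * fs)), n)
  n_lag <- floor(lag_max * fs) + 1L         # lags 0 .. lag_max
  n_T <- min(ceiling(5 * decay_tau * fs), it)
  wgt <- exp(-((seq_len(n_T) - 1) / fs) / decay_tau)
  # b over indices it - (0 .. n_T + n_lag - 2), zero before signal start
  len_b <- n_T + n_lag - 1L
  idx <- it - (seq_len(len_b) - 1L)
  valid <- idx >= 1L
  X <- mcs$data[keep, , drop = FALSE]
  nch <- nrow(X)
  b <- matrix(0, len_b, nch)
  b[valid, ] <- t(X[, idx[valid], drop = FALSE])
  # per-channel DC removal: exponentially weighted mean over the memory window
  xa <- b[seq_len(n_T), , drop = FALSE]
  raw_power <- sum(colSums(xa^2 * wgt))
  mu <- colSums(xa * wgt) / sum(wgt)
  b <- sweep(b, 2, mu)
  a <- sweep(xa, 2, mu) * wgt
  # R_l = sum_T a[T] * b[T + l], all channels at once via FFT correlation
  N <- stats::nextn(len_b + n_T, 2)
  A <- stats::mvfft(rbind(a, matrix(0, N - n_T, nch)))
  Bm <- stats::mvfft(rbind(b, matrix(0, N - len_b, nch)))
  corr <- Re(stats::mvfft(Bm * Conj(A), inverse = TRUE)) / N
  corr <- corr[seq_len(n_lag), , drop = FALSE]
  pa <- corr[1, ]                      # weighted power of the lagless segment
  degenerate <- pa <= 1e-10 * max(raw_power, .Machine$double.xmin)
  if (all(degenerate)) {
    amp <- rep(0, n_lag)
    amp[1] <- 1
  } else if (per_channel_norm) {
    # weighted power of the lagged segment, per lag: sum_T w[T] * b[T + l]^2
    W <- stats::fft(c(wgt, numeric(N - n_T)))
    B2 <- stats::mvfft(rbind(b^2, matrix(0, N - len_b, nch)))
    pb <- Re(stats::mvfft(B2 * Conj(W), inverse = TRUE)) / N
    pb <- pb[seq_len(n_lag), , drop = FALSE]
    live <- !degenerate & pa > 1e-9 * max(pa)
    denom <- sqrt(sweep(pmax(pb[, live, drop = FALSE], 0), 2,
                        1e-12 * pa[live], pmax) *
                  rep(pa[live], each = n_lag))
    amp <- rowMeans(corr[, live, drop = FALSE] / denom)
    amp <- amp / amp[1]
  } else {
    amp <- rowSums(corr)
    amp <- amp / amp[1]
  }
  structure(list(lags = (seq_len(n_lag) - 1) / fs, amplitude = amp,
                 eval_time = it / fs, decay_tau = decay_tau,
                 channel_range = range(mcs$cfs[keep])),
            class = "sacf")
}

channel_mask <- function(mcs, channel_range) {
  if (is.null(channel_range)) return(rep(TRUE, length(mcs$cfs)))
  if (length(channel_range) != 2L) stop("channel_range must be c(f_l, f_u)")
  keep <- mcs$cfs >= channel_range[1] & mcs$cfs <= channel_range[2]
  if (!any(keep)) stop("no channels inside channel_range")
  keep
}

#' @export
print.sacf <- function(x, ...) {
  cat(sprintf("<sacf> %d lags 0-%.4g ms, eval at %.4g s, decay tau %g ms\n",
              length(x$lags), max(x$lags) * 1000, x$eval_time,
              x$decay_tau * 1000))
  invisible(x)
}

#' Running summary autocorrelation
#'
#' One SACF per frame time, each normalized by its own lag-0 value; the
#' short 5-ms memory makes this a dynamic pitch tracker across the stimulus.
#'
#' @param mcs A `"multichannel"` object at stage `"haircell"` or
#'   `"nonlinear"`.
#' @param frame_times Increasing vector of evaluation times in seconds.
#' @param lag_max,decay_tau,channel_range As in [sacf()].
#' @return A list of `"sacf"` objects, one per frame.
#' @export
running_sacf <- function(mcs, frame_times, lag_max = 0.0125,
                         decay_tau = 0.005, channel_range = NULL,
                         per_channel_norm = TRUE) {
  if (length(frame_times) == 0L) stop("frame_times is empty")
  if (is.unsorted(frame_times, strictly = TRUE))
    stop("frame_times must be strictly increasing")
  lapply(frame_times, function(t0)
    sacf(mcs, t0, lag_max = lag_max, decay_tau = decay_tau,
         channel_range = channel_range, per_channel_norm = per_channel_norm))
}

#' Peak-acceptance criteria for pitch estimation
#'
#' The model's "peak at a non-zero lag" needs an operational definition: a
#' local SACF maximum at lag >= `lag_min` (outside the zero-lag main lobe),
#' with normalized height >= `salience_threshold`, topographic prominence
#' >= `prominence`, and — the decisive periodicity test — comparably tall
#' SACF values at twice and three times the peak lag
#' (`harmonic_consistency`). A genuinely periodic drive repeats at every
#' multiple of its period, so its SACF is about as tall at `2 * lag` and
#' `3 * lag` as at `lag`; the transient carrier correlation left by a
#' frequency-drifting sweep decays across lag multiples and fails the test.
#' The defaults accept every 150-ms pure tone in the 300-1000 Hz range and
#' reject 40-ms linear FM sweeps (0.5-2 kHz and 0.6-0.9 kHz, both
#' directions) at every evaluation time.
#'
#' @param lag_min Zero-lag exclusion zone in seconds (> 0).
#' @param salience_threshold Minimum normalized peak height, in (0, 1).
#' @param prominence Minimum peak prominence (height above the higher of the
#'   two flanking minima), in (0, 1).
#' @param octave_tolerance A periodic signal repeats at every multiple of its
#'   period, so qualifying peaks occur at all period multiples with nearly
#'   equal salience; among qualifying peaks within this fraction of the best
#'   salience, the smallest lag wins (the standard subharmonic-error
#'   correction). In `[0, 1)`.
#' @param harmonic_consistency Minimum ratio of the SACF amplitude near two
#'   and three times the tallest qualifying peak's lag (within +-10% of each
#'   multiple) to that peak's amplitude, required for the peak to count as
#'   periodicity rather than transient correlation. Multiples beyond the lag
#'   axis are not checked. In `[0, 1)`; 0 disables.
#' @return An object of class `"peak_criteria"`.
#' @export
peak_criteria <- function(lag_min = 0.0005, salience_threshold = 0.30,
                          prominence = 0.05, octave_tolerance = 0.15,
                          harmonic_consistency = 0.87) {
  if (lag_min <= 0) stop("lag_min must be positive")
  if (salience_threshold <= 0 || salience_threshold >= 1)
    stop("salience_threshold must be in (0, 1)")
  if (prominence <= 0 || prominence >= 1)
    stop("prominence must be in (0, 1)")
  if (octave_tolerance < 0 || octave_tolerance >= 1)
    stop("octave_tolerance must be in [0, 1)")
  if (harmonic_consistency < 0 || harmonic_consistency >= 1)
    stop("harmonic_consistency must be in [0, 1)")
  structure(list(lag_min = lag_min, salience_threshold = salience_threshold,
                 prominence = prominence,
                 octave_tolerance = octave_tolerance,
                 harmonic_consistency = harmonic_consistency),
            class = "peak_criteria")
}

# local maxima with prominence: for each interior local max, prominence is
# height minus the higher of the lowest points walking out to the nearest
# higher sample on each side (or the series end).
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  idx <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  idx
}

peak_prominence <- function(y, i) {
  n <- length(y)
  left_min <- min(y[seq_len(i)])
  j <- i
  while (j > 1 && y[j - 1] <= y[i]) j <- j - 1
  left_min <- min(y[j:i])
  k <- i
  while (k < n && y[k + 1] <= y[i]) k <- k + 1
  right_min <- min(y[i:k])
  y[i] - max(left_min, right_min)
}

#' Estimate pitch from a SACF
#'
#' Scans the normalized SACF for local maxima satisfying the
#' [peak_criteria()]; the highest-salience qualifying peak becomes the pitch
#' estimate (frequency = 1/lag, lag refined by parabolic interpolation).
#' When no peak qualifies the result has `found = FALSE` — the explicit
#' "no pitch estimate" outcome.
#'
#' @param s A `"sacf"` object.
#' @param criteria A [peak_criteria()].
#' @return An object of class `"pitch_estimate"`: `found`, and when found,
#'   `lag` (s, parabolic-refined), `lag_grid` (s, the winning lag sample
#'   before refinement), `frequency` (Hz, `1/lag`), `salience`, plus the
#'   criteria used.
#' @export
estimate_pitch <- function(s, criteria = peak_criteria()) {
  stopifnot(inherits(s, "sacf"), inherits(criteria, "peak_criteria"))
  y <- s$amplitude
  cand <- find_peaks(y)
  cand <- cand[s$lags[cand] >= criteria$lag_min]
  cand <- cand[y[cand] >= criteria$salience_threshold]
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
    cand <- cand[prom >= criteria$prominence]
  }
  if (length(cand) && criteria$harmonic_consistency > 0) {
    # the dominant periodicity hypothesis must self-verify: if the tallest
    # qualifying peak does not repeat at two and three times its lag, the
    # pattern is transient correlation, not periodicity — no pitch at all
    tallest <- cand[which.max(y[cand])]
    for (k in c(2, 3)) {
      lk <- k * s$lags[tallest]
      if (lk > max(s$lags)) next       # repetition unobservable at this k
      sel <- s$lags >= 0.9 * lk & s$lags <= 1.1 * lk
      if (max(y[sel]) < criteria$harmonic_consistency * y[tallest]) {
        cand <- integer(0)
        break
      }
    }
  }
  if (!length(cand)) {
    return(structure(list(found = FALSE, lag = NA_real_, lag_grid = NA_real_,
                          frequency = NA_real_, salience = NA_real_,
                          criteria = criteria),
                     class = "pitch_estimate"))
  }
  top <- max(y[cand])
  near <- cand[y[cand] >= top * (1 - criteria$octave_tolerance)]
  best <- near[which.min(s$lags[near])]
  # parabolic refinement around the winning sample
  lag <- s$lags[best]; sal <- y[best]
  if (best > 1 && best < length(y)) {
    b1 <- (y[best + 1] - y[best - 1]) / 2
    c2 <- y[best - 1] - 2 * y[best] + y[best + 1]
    if (c2 < 0) {
      shift <- -b1 / c2            # vertex of the fitted parabola, in samples
      if (abs(shift) <= 1) {
        dl <- s$lags[2] - s$lags[1]
        lag <- lag + shift * dl
        sal <- y[best] + 0.5 * b1 * shift
      }
    }
  }
  structure(list(found = TRUE, lag = lag, lag_grid = s$lags[best],
                 frequency = 1 / lag, salience = sal, criteria = criteria),
            class = "pitch_estimate")
}

#' @export
print.pitch_estimate <- function(x, ...) {
  if (x$found) {
    cat(sprintf("<pitch> found: lag %.4g ms, frequency %.1f Hz, salience %.3f\n",
                x$lag * 1000, x$frequency, x$salience))
  } else {
    cat("<pitch> no pitch estimate (no qualifying peak at a non-zero lag)\n")
  }
  invisible(x)
}

#' SACF curvature (discrete second derivative)
#'
#' Central second difference of the normalized amplitude with respect to lag,
#' plus the lags at which its sign changes. A sweep's SACF can change
#' curvature sign at non-zero lag without producing any qualifying peak.
#'
#' @param s A `"sacf"` object with at least 3 lag samples.
#' @return A list with `lags` (interior lags), `curvature` (per-lag signed
#'   second difference) and `sign_change_lags` (lags where the curvature
#'   crosses zero).
#' @export
sacf_curvature <- function(s) {
  stopifnot(inherits(s, "sacf"))
  y <- s$amplitude
  n <- length(y)
  if (n < 3) stop("SACF too short for curvature (need >= 3 lag samples)")
  curv <- y[3:n] - 2 * y[2:(n - 1)] + y[1:(n - 2)]
  lags <- s$lags[2:(n - 1)]
  sgn <- sign(curv)
  nz <- which(sgn != 0)
  changes <- integer(0)
  if (length(nz) > 1) {
    flips <- which(diff(sgn[nz]) != 0)
    changes <- nz[flips + 1]
  }
  list(lags = lags, curvature = curv, sign_change_lags = lags[changes])
}
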