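# Independent oracles, written as plain loops so they share no code with the
# package's vectorized paths.

# Literal discretized double sum of the exponentially weighted
# autocorrelation, mirroring the package's discretization conventions
# (memory truncation at 5 * decay_tau, silence before sample 1, per-channel
# weighted mean removal, and either correlation-coefficient or raw channel
# integration), computed with explicit loops over channels, lags and past
# time.
sacf_bruteforce <- function(mcs, eval_time, lag_max, decay_tau = 0.005,
                            per_channel_norm = TRUE) {
  fs <- mcs$sample_rate
  X <- mcs$data
  nch <- nrow(X)
  n <- ncol(X)
  it <- min(max(1L, round(eval_time * fs)), n)
  n_lag <- floor(lag_max * fs) + 1L
  n_T <- min(ceiling(5 * decay_tau * fs), it)
  wgt <- exp(-((seq_len(n_T) - 1) / fs) / decay_tau)
  val_at <- function(ch, i) if (i >= 1L) X[ch, i] else 0
  corr <- matrix(0, n_lag, nch)
  pb <- matrix(0, n_lag, nch)
  pa <- numeric(nch)
  mu <- numeric(nch)
  raw_power <- 0
  for (ch in seq_len(nch)) {
    sa <- 0
    for (Ti in seq_len(n_T)) {
      x <- val_at(ch, it - (Ti - 1L))
      sa <- sa + wgt[Ti] * x
      raw_power <- raw_power + wgt[Ti] * x^2
    }
    mu[ch] <- sa / sum(wgt)
    for (l in seq_len(n_lag) - 1L) {
      s <- 0; p <- 0
      for (Ti in seq_len(n_T)) {
        xa <- val_at(ch, it - (Ti - 1L)) - mu[ch]
        xb <- val_at(ch, it - (Ti - 1L) - l) - mu[ch]
        s <- s + wgt[Ti] * xa * xb
        p <- p + wgt[Ti] * xb^2
      }
      corr[l + 1L, ch] <- s
      pb[l + 1L, ch] <- p
    }
    pa[ch] <- corr[1L, ch]
  }
  degenerate <- pa <= 1e-10 * max(raw_power, .Machine$double.xmin)
  if (all(degenerate)) {
    amp <- rep(0, n_lag); amp[1] <- 1
  } else if (per_channel_norm) {
    live <- which(!degenerate & pa > 1e-9 * max(pa))
    acc <- numeric(n_lag)
    for (ch in live) {
      for (l in seq_len(n_lag)) {
        denom <- sqrt(max(pb[l, ch], 1e-12 * pa[ch]) * pa[ch])
        acc[l] <- acc[l] + corr[l, ch] / denom
      }
    }
    amp <- acc / length(live)
    amp <- amp / amp[1]
  } else {
    amp <- rowSums(corr)
    amp <- amp / amp[1]
  }
  list(lags = (seq_len(n_lag) - 1) / fs, amplitude = amp)
}

# wrap a plain channels x time matrix as hair-cell stage output
as_haircell <- function(data, cfs, sample_rate) {
  structure(list(data = data, cfs = cfs, sample_rate = sample_rate,
                 stage = "haircell"), class = "multichannel")
}

# build a synthetic SACF object directly (for peak-criteria logic tests)
synthetic_sacf <- function(lags, amplitude) {
  structure(list(lags = lags, amplitude = amplitude,
                 eval_time = max(lags) * 2, decay_tau = 0.005,
                 channel_range = c(300, 3000)), class = "sacf")
}

# instantaneous frequency by differentiating the phase of the analytic
# signal (frequency-domain Hilbert transform, independent of the package's)
instantaneous_frequency <- function(x, fs) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  z <- stats::fft(X * h, inverse = TRUE) / n
  ph <- Arg(z)
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  dph * fs / (2 * pi)
}

full_model <- function(w, n_channels = 50, sample_rate = 44100) {
  fb <- design_filterbank(n_channels, 300, 3000, sample_rate)
  ihc_transduce(apply_filterbank(w, fb))
}
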