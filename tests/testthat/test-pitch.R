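test_that("vectorized SACF equals the literal double-sum on small instances", {
  fs <- 8000
  set.seed(11)
  # three channels: a 4-ms pulse train, a 500-Hz rectified tone, noise
  n <- round(0.05 * fs)
  t <- (seq_len(n) - 1) / fs
  pulses <- as.numeric(seq_len(n) %% round(0.004 * fs) == 1)
  tone <- pmax(sin(2 * pi * 500 * t), 0)
  noise <- abs(stats::rnorm(n, sd = 0.3)) + 0.05
  mcs <- as_haircell(rbind(pulses, tone, noise), c(400, 500, 800), fs)
  for (norm in c(TRUE, FALSE)) {
    fast <- sacf(mcs, eval_time = 0.05, lag_max = 0.01,
                 per_channel_norm = norm)
    slow <- sacf_bruteforce(mcs, eval_time = 0.05, lag_max = 0.01,
                            per_channel_norm = norm)
    expect_equal(fast$amplitude, slow$amplitude, tolerance = 1e-9)
    expect_equal(fast$lags, slow$lags)
  }
  # mid-signal evaluation, different decay
  fast <- sacf(mcs, eval_time = 0.03, lag_max = 0.008, decay_tau = 0.002)
  slow <- sacf_bruteforce(mcs, eval_time = 0.03, lag_max = 0.008,
                          decay_tau = 0.002)
  expect_equal(fast$amplitude, slow$amplitude, tolerance = 1e-9)
})

test_that("single-channel 4-ms pulse train peaks at 4 and 8 ms", {
  fs <- 8000
  n <- round(0.08 * fs)
  pulses <- as.numeric(seq_len(n) %% round(0.004 * fs) == 1)
  mcs <- as_haircell(matrix(pulses, 1), 500, fs)
  s <- sacf(mcs, eval_time = 0.08, lag_max = 0.0105)
  near <- function(lag_s) {
    sel <- abs(s$lags - lag_s) <= 2 / fs
    max(s$amplitude[sel])
  }
  expect_gt(near(0.004), 0.8)
  expect_gt(near(0.008), 0.8)
  off <- s$lags > 0.001 & (abs(s$lags - 0.004) > 0.001) &
    (abs(s$lags - 0.008) > 0.001)
  expect_lt(max(s$amplitude[off]), 0.5)
})

test_that("SACF is 1 at lag 0 and maximal there for noise input", {
  fs <- 8000
  set.seed(4)
  noise <- abs(stats::rnorm(round(0.5 * fs))) + 0.01
  mcs <- as_haircell(matrix(noise, 1), 1000, fs)
  s <- sacf(mcs, eval_time = 0.5, lag_max = 0.0125, decay_tau = 1)
  expect_equal(s$amplitude[1], 1)
  expect_true(all(s$amplitude[-1] < 1))
  expect_true(all(is.finite(s$amplitude)))
  expect_true(all(diff(s$lags) > 0))
})

test_that("SACF rejects invalid evaluation setups", {
  fs <- 8000
  mcs <- as_haircell(matrix(1 + numeric(800), 1), 500, fs)
  expect_error(sacf(mcs, eval_time = 0.2), "beyond signal end")
  expect_error(sacf(mcs, eval_time = 0.05, lag_max = -1), "lag_max")
  expect_error(sacf(mcs, eval_time = 0.01, lag_max = 0.0125), "below eval_time")
  fbout <- structure(list(data = matrix(0, 1, 800), cfs = 500,
                          sample_rate = fs, stage = "filterbank"),
                     class = "multichannel")
  expect_error(sacf(fbout, eval_time = 0.05, lag_max = 0.01), "hair-cell")
})

test_that("a frame with almost no history carries no pitch", {
  fs <- 16000
  # tone starting at 13 ms, evaluated at 14 ms: one 1-ms sliver of history
  pre <- numeric(round(0.013 * fs))
  tone <- make_pure_tone(500, 0.1, fs)
  mcs <- as_haircell(matrix(c(pre, pmax(tone$samples, 0)), 1), 500, fs)
  s <- sacf(mcs, eval_time = 0.014, lag_max = 0.0125)
  expect_equal(s$amplitude[1], 1)
  expect_false(estimate_pitch(s)$found)
})

test_that("running SACF validates frames and tracks a stationary tone", {
  fs <- 16000
  hc <- full_model(make_pure_tone(500, 0.12, fs), n_channels = 16,
                   sample_rate = fs)
  expect_error(running_sacf(hc, numeric(0)), "empty")
  expect_error(running_sacf(hc, c(0.05, 0.04)), "increasing")
  frames <- seq(0.04, 0.12, by = 0.01)
  rs <- running_sacf(hc, frames)
  expect_length(rs, length(frames))
  est <- lapply(rs, estimate_pitch)
  found <- vapply(est, function(e) e$found, logical(1))
  expect_true(all(found))
  lags <- vapply(est, function(e) e$lag, numeric(1))
  expect_lt(stats::sd(lags) / mean(lags), 0.05)
})

test_that("peak criteria validate their fields", {
  expect_error(peak_criteria(lag_min = 0), "lag_min")
  expect_error(peak_criteria(salience_threshold = 1.2), "salience")
  expect_error(peak_criteria(prominence = 0), "prominence")
  expect_error(peak_criteria(octave_tolerance = 1), "octave")
  expect_error(peak_criteria(harmonic_consistency = 1), "harmonic")
})

test_that("peak selection honours thresholds, prominence and repetition", {
  lags <- seq(0, 0.0125, by = 1 / 44100)
  # periodic pattern: damped cosine with 2-ms period
  periodic <- synthetic_sacf(lags, cos(2 * pi * lags / 0.002) *
                               exp(-lags / 0.05))
  p <- estimate_pitch(periodic)
  expect_true(p$found)
  expect_equal(p$frequency, 500, tolerance = 0.01)
  expect_lte(abs(p$lag_grid - 0.002), 1.01 / 44100)
  # threshold above the peak height: nothing qualifies
  p2 <- estimate_pitch(periodic, peak_criteria(salience_threshold = 0.995))
  expect_false(p2$found)

  # an isolated bump at 2 ms that never repeats is transient correlation
  bump <- synthetic_sacf(lags, exp(-(lags)^2 / (2e-4)^2) +
                           0.8 * exp(-(lags - 0.002)^2 / (2e-4)^2))
  expect_false(estimate_pitch(bump)$found)
  # same bump accepted when the repetition test is disabled
  expect_true(estimate_pitch(bump,
    peak_criteria(harmonic_consistency = 0))$found)

  # subharmonic correction: slightly taller peak at twice the period still
  # yields the fundamental
  y <- cos(2 * pi * lags / 0.002) * exp(-lags / 0.1) +
    0.05 * cos(2 * pi * lags / 0.004)
  sub <- synthetic_sacf(lags, y / y[1])
  p3 <- estimate_pitch(sub)
  expect_true(p3$found)
  expect_equal(p3$frequency, 500, tolerance = 0.02)
})

test_that("curvature reports sign changes around true peaks", {
  lags <- seq(0, 0.0125, by = 1 / 44100)
  tone_like <- synthetic_sacf(lags, cos(2 * pi * lags / 0.002) *
                                exp(-lags / 0.05))
  cv <- sacf_curvature(tone_like)
  expect_length(cv$curvature, length(lags) - 2)
  # sign changes bracket the 2-ms peak
  expect_true(any(cv$sign_change_lags > 0.001 & cv$sign_change_lags < 0.002))
  expect_true(any(cv$sign_change_lags > 0.002 & cv$sign_change_lags < 0.003))

  quad <- synthetic_sacf(lags, 1 - 50 * lags^2)
  cvq <- sacf_curvature(quad)
  expect_length(cvq$sign_change_lags, 0)
  expect_lt(diff(range(cvq$curvature)), 1e-12)

  short <- synthetic_sacf(c(0, 1e-4), c(1, 0.5))
  expect_error(sacf_curvature(short), "too short")
})
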