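test_that("filterbank CFs are geometric from cf_low to cf_high", {
  fb <- design_filterbank(50, 300, 3000, 44100)
  expect_length(fb$cfs, 50)
  expect_equal(fb$cfs[1], 300)
  expect_equal(fb$cfs[50], 3000)
  ratios <- fb$cfs[-1] / fb$cfs[-50]
  expect_lt(max(abs(ratios / 10^(1 / 49) - 1)), 1e-12)

  fb2 <- design_filterbank(2, 300, 3000, 44100)
  expect_equal(fb2$cfs, c(300, 3000))

  # geometric mean of the band falls between the two middle channels
  gm <- sqrt(300 * 3000)
  expect_lt(fb$cfs[25], gm)
  expect_gt(fb$cfs[26], gm)
  expect_equal(gm, 948.6833, tolerance = 1e-4)

  expect_error(design_filterbank(50, 3000, 300, 44100), "cf_low")
  expect_error(design_filterbank(50, 300, 30000, 44100), "Nyquist")
})

test_that("gammatone filtering is linear with on-CF dominance", {
  fb <- design_filterbank(12, 300, 3000, 16000)
  tone <- make_pure_tone(500, 0.08, 16000)
  mcs <- apply_filterbank(tone, fb)
  expect_identical(mcs$stage, "filterbank")
  rms <- sqrt(rowMeans(mcs$data^2))
  expect_equal(which.max(rms), which.min(abs(fb$cfs - 500)))

  half <- waveform(tone$samples / 2, 16000)
  mcs_half <- apply_filterbank(half, fb)
  expect_equal(mcs_half$data, mcs$data / 2, tolerance = 1e-9)

  expect_error(apply_filterbank(waveform(numeric(0), 16000), fb), "empty")
  expect_error(apply_filterbank(make_pure_tone(500, 0.05, 44100), fb),
               "sample rates")
})

test_that("sweep response ridge moves up in frequency over time", {
  fs <- 44100
  fb <- design_filterbank(20, 300, 3000, fs)
  up <- make_linear_fm(sweep_spec(500, 2000, 0.040), fs)
  mcs <- apply_filterbank(up, fb)
  in_band <- which(fb$cfs >= 500 & fb$cfs <= 2000)
  peak_time <- apply(abs(mcs$data[in_band, ]), 1, which.max) / fs
  expect_gt(stats::cor(peak_time, fb$cfs[in_band], method = "spearman"), 0.9)
})

test_that("gammatone impulse responses decay within the 100-ms window", {
  fs <- 16000
  fb <- design_filterbank(10, 300, 3000, fs)
  imp <- waveform(c(1, numeric(round(0.1 * fs) - 1)), fs)
  mcs <- apply_filterbank(imp, fb)
  n <- ncol(mcs$data)
  tail_idx <- seq.int(round(0.9 * n), n)
  for (ch in seq_len(nrow(mcs$data))) {
    e_total <- sum(mcs$data[ch, ]^2)
    e_tail <- sum(mcs$data[ch, tail_idx]^2)
    expect_lt(e_tail, 0.01 * e_total)
  }
})

test_that("hair-cell stage rests at a constant spontaneous level on silence", {
  fs <- 16000
  fb <- design_filterbank(5, 300, 3000, fs)
  silence <- waveform(numeric(round(0.05 * fs)), fs)
  hc <- ihc_transduce(apply_filterbank(silence, fb))
  expect_identical(hc$stage, "haircell")
  expect_gte(min(hc$data), 0)
  expect_gt(mean(hc$data), 0)                       # spontaneous level
  expect_lt(max(hc$data) - min(hc$data), 1e-6 * mean(hc$data))
})

test_that("hair-cell output is nonnegative and preserves phase locking", {
  fs <- 16000
  fb <- design_filterbank(9, 300, 3000, fs)
  hc <- ihc_transduce(apply_filterbank(make_pure_tone(500, 0.1, fs), fb))
  expect_gte(min(hc$data), 0)
  ch <- which.min(abs(fb$cfs - 500))
  x <- hc$data[ch, ]
  x <- x[round(length(x) / 2):length(x)]            # steady state
  spec <- abs(stats::fft(x - mean(x)))
  freqs <- (seq_along(spec) - 1) * fs / length(spec)
  half <- freqs <= fs / 2 & freqs > 100
  expect_equal(freqs[half][which.max(spec[half])], 500, tolerance = 0.03 * 500)

  expect_error(ihc_transduce(hc), "filterbank stage")
})

test_that("power nonlinearity preserves sign and ordering", {
  fs <- 16000
  fb <- design_filterbank(5, 300, 3000, fs)
  hc <- ihc_transduce(apply_filterbank(make_pure_tone(500, 0.05, fs), fb))
  sq <- apply_nonlinearity(hc, 2)
  expect_identical(sq$stage, "nonlinear")
  expect_gte(min(sq$data), 0)
  expect_equal(sq$data, hc$data^2)

  fbout <- apply_filterbank(make_pure_tone(500, 0.05, fs), fb)
  cu <- apply_nonlinearity(fbout, 3)
  expect_equal(sign(cu$data), sign(fbout$data))
  small <- abs(fbout$data) <= 1
  expect_true(all(abs(cu$data[small]) <= abs(fbout$data[small]) + 1e-15))

  expect_error(apply_nonlinearity(hc, 4), "exponent")
})
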