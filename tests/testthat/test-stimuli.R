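test_that("pure tone has the right length, spectrum and autocorrelation", {
  w <- make_pure_tone(500, 0.150, 44100, 0.005)
  expect_s3_class(w, "waveform")
  expect_length(w$samples, 6615)
  expect_lte(max(abs(w$samples)), 1)

  spec <- abs(stats::fft(w$samples))[1:3000]
  freqs <- (0:2999) * 44100 / 6615
  expect_equal(freqs[which.max(spec)], 500, tolerance = 0.01)

  # raw-waveform autocorrelation peaks at the 2.0-ms period
  ac <- stats::acf(w$samples, lag.max = 150, plot = FALSE)$acf[-1]
  search <- 23:150                      # beyond the zero-lag main lobe
  lag_ms <- search[which.max(ac[search])] / 44.1
  expect_equal(lag_ms, 2.0, tolerance = 0.03)
})

test_that("unramped tone follows the zero-phase convention with RMS 1/sqrt(2)", {
  for (f in c(250, 441, 1000)) {
    w <- make_pure_tone(f, 0.1, 44100, ramp = 0)
    expect_identical(w$samples[1], 0)
    expect_equal(sqrt(mean(w$samples^2)), 1 / sqrt(2), tolerance = 1e-3)
  }
})

test_that("pure tone rejects invalid arguments", {
  expect_error(make_pure_tone(23000, 0.1, 44100), "Nyquist")
  expect_error(make_pure_tone(500, -0.1, 44100), "duration")
  expect_error(make_pure_tone(500, 0.008, 44100, ramp = 0.005), "ramp")
})

test_that("linear FM sweep has the specified instantaneous frequency", {
  w <- make_linear_fm(sweep_spec(500, 2000, 0.040, 0.005), 44100)
  expect_length(w$samples, 1764)
  fi <- instantaneous_frequency(w$samples, 44100)
  i_mid <- round(0.020 * 44100)
  expect_equal(median(fi[(i_mid - 20):(i_mid + 20)]), 1250,
               tolerance = 0.01 * 1250)
  # quarter point of an 0.5-2 kHz sweep: 875 Hz
  i_q <- round(0.010 * 44100)
  expect_equal(median(fi[(i_q - 20):(i_q + 20)]), 875, tolerance = 0.01 * 875)
})

test_that("degenerate sweep equals a pure tone and down equals reversed up", {
  tone <- make_pure_tone(700, 0.05, 44100)
  sw <- make_linear_fm(sweep_spec(700, 700, 0.05), 44100)
  expect_equal(sw$samples, tone$samples, tolerance = 1e-12)

  up <- make_linear_fm(sweep_spec(500, 2000, 0.040), 44100)
  down <- make_linear_fm(sweep_spec(2000, 500, 0.040), 44100)
  expect_equal(down$samples, rev(up$samples), tolerance = 1e-9)
  expect_error(sweep_spec(500, 2000, 0.008, ramp = 0.005), "ramp")
})

test_that("tone pair applies the semitone rule and duration arithmetic", {
  w <- make_tone_pair(500, +1, 0.150, 0.350, 44100)
  expect_equal(attr(w, "comparison_freq"), 500 * 2^(1 / 12))
  expect_equal(attr(w, "comparison_freq"), 529.7315, tolerance = 1e-4)
  expect_equal(duration(w), 0.650, tolerance = 1e-9)

  single <- make_tone_pair(500, 0, 0.150, 0, 44100)
  expect_length(single$samples, 2 * 6615)
  expect_error(make_tone_pair(500, 1, 0.1, -0.1), "gap")
  # comparison above Nyquist rejected
  expect_error(make_tone_pair(21000, +12, 0.1, 0.1, 44100), "Nyquist")
})

test_that("rhythmic cue produces onsets on the cue period", {
  cue <- make_rhythmic_cue(rhythmic_cue_spec(rate = 1.7, isi = 0.6), 44100)
  expect_equal(cue$onsets, c(0, 0.6, 1.2, 1.8))
  expect_equal(duration(cue$wave), 2.1, tolerance = 1e-6)

  cue2 <- make_rhythmic_cue(rhythmic_cue_spec(rate = 2), 44100)
  expect_equal(cue2$onsets, c(0, 0.5, 1.0, 1.5))
  spec2 <- rhythmic_cue_spec(rate = 2)
  expect_equal(spec2$tone_duration, 0.25)

  single <- make_rhythmic_cue(rhythmic_cue_spec(rate = 2, n_cycles = 1,
                                                duty = 1), 44100)
  expect_equal(duration(single$wave), 0.5, tolerance = 1e-6)
  expect_error(rhythmic_cue_spec(rate = 2, duty = 0), "duty")
})

test_that("continuous cue matches the rhythmic sequence's span", {
  sp <- rhythmic_cue_spec(rate = 1.7, isi = 0.6)
  expect_equal(duration(make_continuous_cue(sp, 44100)), 2.1,
               tolerance = 1e-6)
  sp2 <- rhythmic_cue_spec(rate = 2)
  expect_equal(duration(make_continuous_cue(sp2, 44100)), 1.75,
               tolerance = 1e-6)
  # duty = 1: identical duration to the rhythmic waveform span
  sp3 <- rhythmic_cue_spec(rate = 2, duty = 1)
  expect_equal(duration(make_continuous_cue(sp3, 44100)),
               duration(make_rhythmic_cue(sp3, 44100)$wave),
               tolerance = 1e-6)
  # alternative whole-cycle convention
  expect_equal(duration(make_continuous_cue(sp2, 44100, full_cycles = TRUE)),
               2.0, tolerance = 1e-6)
})

test_that("every generated stimulus keeps peak <= 1 and exact sample counts", {
  gens <- list(
    make_pure_tone(500, 0.123, 22050),
    make_linear_fm(sweep_spec(600, 900, 0.040), 22050),
    make_tone_pair(440, -1, 0.1, 0.05, 22050),
    make_rhythmic_cue(rhythmic_cue_spec(rate = 2.5), 22050)$wave,
    make_continuous_cue(rhythmic_cue_spec(rate = 1.4), 22050)
  )
  for (w in gens) expect_lte(max(abs(w$samples)), 1)
  expect_length(make_pure_tone(500, 0.123, 22050)$samples,
                round(0.123 * 22050))
})

test_that("audio demo presets match their published parameters", {
  d1 <- audio_demo("S1")
  expect_equal(d1$spec_up$f_start, 5500)
  expect_equal(d1$spec_up$f_end, 7000)
  expect_equal(d1$spec_up$duration, 0.040)
  expect_equal(d1$spec_down$f_start, 7000)

  d2 <- audio_demo("S2")
  expect_equal(d2$spec_up$duration, 0.010)
  expect_equal(d2$spec_up$ramp, 0.005)
  expect_equal(c(d2$spec_up$f_start, d2$spec_up$f_end), c(500, 2000))

  expect_equal(audio_demo("S4")$spec_up$f_end, 900)
  expect_error(audio_demo("S9"))
})
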