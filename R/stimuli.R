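#' @title Stimulus synthesis
#' @name stimuli
#' @description
#' Generators for every stimulus class the analysis pipeline consumes: pure
#' tones, tone pairs separated by a semitone step, linear FM sweeps, rhythmic
#' cue sequences (square-wave gating, 50% duty cycle by default) and their
#' duration-matched continuous counterparts. All tones start at zero phase and
#' carry raised-cosine on/off ramps (default 5 ms).
NULL

# raised-cosine on/off ramp, in place
apply_ramp <- function(x, sample_rate, ramp) {
  if (ramp <= 0) return(x)
  nr <- round(ramp * sample_rate)
  if (nr < 1) return(x)
  if (2 * nr > length(x)) stop("ramps longer than the signal")
  # half-cosine rise from 0 to 1 over nr samples
  env <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
  x[seq_len(nr)] <- x[seq_len(nr)] * env
  n <- length(x)
  x[(n - nr + 1):n] <- x[(n - nr + 1):n] * rev(env)
  x
}

check_freq <- function(freq, sample_rate) {
  if (any(freq <= 0)) stop("frequency must be positive")
  if (any(freq >= sample_rate / 2))
    stop(sprintf("frequency %g Hz is at or above Nyquist (%g Hz)",
                 max(freq), sample_rate / 2))
}

#' Synthesize a pure tone
#'
#' Zero-phase sinusoid with raised-cosine on/off ramps. Peak amplitude is 1
#' before ramping.
#'
#' @param freq Tone frequency in Hz (must be below Nyquist).
#' @param duration Duration in seconds.
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @param ramp Rise/decay time in seconds (default 0.005); `2 * ramp` must not
#'   exceed `duration`.
#' @return A [waveform()] of `round(duration * sample_rate)` samples.
#' @examples
#' tone <- make_pure_tone(500, 0.150)
#' duration(tone)
#' @export
make_pure_tone <- function(freq, duration, sample_rate = 44100, ramp = 0.005) {
  check_freq(freq, sample_rate)
  if (duration <= 0) stop("duration must be positive")
  if (2 * ramp > duration) stop("2 * ramp must not exceed duration")
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  x <- sin(2 * pi * freq * t)
  waveform(apply_ramp(x, sample_rate, ramp), sample_rate)
}

#' Linear FM sweep specification
#'
#' @param f_start,f_end Edge frequencies in Hz (both positive).
#' @param duration Sweep duration in seconds.
#' @param ramp Rise/decay time in seconds; `2 * ramp <= duration`.
#' @return An object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(f_start, f_end, duration, ramp = 0.005) {
  if (f_start <= 0 || f_end <= 0) stop("edge frequencies must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (2 * ramp > duration) stop("2 * ramp must not exceed duration")
  structure(list(f_start = f_start, f_end = f_end,
                 duration = duration, ramp = ramp),
            class = "sweep_spec")
}

#' Synthesize a linear FM sweep
#'
#' The instantaneous frequency interpolates linearly from `f_start` to `f_end`
#' over the sweep; the phase is its running integral, so at the midpoint the
#' instantaneous frequency equals the arithmetic mean of the edges. Raised
#' cosine on/off ramps are applied. A degenerate sweep (`f_start == f_end`)
#' equals a pure tone.
#'
#' Down sweeps (`f_start > f_end`) are synthesized as the exact time reversal
#' of the matching up sweep. Since the ramps are symmetric this reverses the
#' instantaneous-frequency trajectory sample for sample and makes the up/down
#' magnitude-spectrum identity hold exactly rather than to discretization
#' error; only the phase spectra differ.
#'
#' @param spec A [sweep_spec()].
#' @param sample_rate Sampling rate in Hz (default 44100).
#' @return A [waveform()].
#' @examples
#' up <- make_linear_fm(sweep_spec(500, 2000, 0.040), 44100)
#' @export
make_linear_fm <- function(spec, sample_rate = 44100) {
  stopifnot(inherits(spec, "sweep_spec"))
  check_freq(c(spec$f_start, spec$f_end), sample_rate)
  if (spec$f_start > spec$f_end) {
    up <- make_linear_fm(sweep_spec(spec$f_end, spec$f_start,
                                    spec$duration, spec$ramp), sample_rate)
    return(waveform(rev(up$samples), sample_rate))
  }
  n <- round(spec$duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  # phase(t) = 2*pi * (f_start*t + (f_end - f_start) * t^2 / (2*duration))
  k <- (spec$f_end - spec$f_start) / spec$duration
  phase <- 2 * pi * (spec$f_start * t + 0.5 * k * t^2)
  x <- sin(phase)
  waveform(apply_ramp(x, sample_rate, spec$ramp), sample_rate)
}

#' Synthesize a standard/comparison tone pair
#'
#' Two sequential pure tones separated by a silent gap: a standard tone and a
#' comparison tone offset by a signed number of semitones (frequency ratio
#' `2^(semitone_offset/12)`). Segments are ramped independently; no phase
#' continuity across the gap is imposed.
#'
#' @param standard_freq Standard tone frequency in Hz.
#' @param semitone_offset Signed semitone count for the comparison tone.
#' @param tone_duration Duration of each tone in seconds.
#' @param gap Silent gap between the tones in seconds (non-negative).
#' @param sample_rate Sampling rate in Hz.
#' @param ramp Rise/decay time per tone in seconds.
#' @return A [waveform()] with attribute `"comparison_freq"` (Hz).
#' @examples
#' pair <- make_tone_pair(500, +1, 0.150, 0.350)
#' attr(pair, "comparison_freq")  # 500 * 2^(1/12)
#' @export
make_tone_pair <- function(standard_freq, semitone_offset, tone_duration, gap,
                           sample_rate = 44100, ramp = 0.005) {
  if (gap < 0) stop("gap must be non-negative")
  comparison_freq <- standard_freq * 2^(semitone_offset / 12)
  check_freq(c(standard_freq, comparison_freq), sample_rate)
  std <- make_pure_tone(standard_freq, tone_duration, sample_rate, ramp)
  cmp <- make_pure_tone(comparison_freq, tone_duration, sample_rate, ramp)
  silence <- numeric(round(gap * sample_rate))
  w <- waveform(c(std$samples, silence, cmp$samples), sample_rate)
  attr(w, "comparison_freq") <- comparison_freq
  w
}

#' Rhythmic cue specification
#'
#' A sequence of `n_cycles` gated pure tones at a repetition `rate` (Hz), each
#' tone lasting `duty / rate` seconds (square-wave gating at the given duty
#' cycle).
#'
#' @param rate Repetition rate in Hz; the inter-stimulus interval (ISI) is
#'   `1 / rate`.
#' @param n_cycles Number of cue tones (>= 1).
#' @param duty On-fraction of each cycle, in (0, 1].
#' @param carrier_freq Carrier frequency of the cue tones in Hz.
#' @param ramp Per-tone rise/decay in seconds.
#' @param isi Optional exact inter-stimulus interval in seconds, overriding
#'   `1 / rate` (nominal rates like 1.7 Hz are conventionally paired with a
#'   round ISI of 600 ms).
#' @return An object of class `"rhythmic_cue_spec"`.
#' @export
rhythmic_cue_spec <- function(rate, n_cycles = 4, duty = 0.5,
                              carrier_freq = 1000, ramp = 0.005,
                              isi = NULL) {
  if (is.null(isi)) {
    if (rate <= 0) stop("rate must be positive")
    isi <- 1 / rate
  } else {
    if (isi <= 0) stop("isi must be positive")
    rate <- 1 / isi
  }
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  if (duty <= 0 || duty > 1) stop("duty must be in (0, 1]")
  structure(list(rate = rate, n_cycles = as.integer(n_cycles), duty = duty,
                 carrier_freq = carrier_freq, ramp = ramp,
                 isi = isi, tone_duration = duty * isi),
            class = "rhythmic_cue_spec")
}

#' Synthesize a rhythmic cue sequence
#'
#' `n_cycles` tones with onsets at `k / rate` (k = 0, ..., n-1), each of
#' duration `duty / rate`. The waveform ends at the last tone's offset; onset
#' times are returned for downstream temporal-expectancy computation.
#'
#' @param spec A [rhythmic_cue_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @return A list with `wave` (a [waveform()]) and `onsets` (numeric vector of
#'   onset times in seconds).
#' @examples
#' cue <- make_rhythmic_cue(rhythmic_cue_spec(rate = 1.7), 44100)
#' cue$onsets
#' @export
make_rhythmic_cue <- function(spec, sample_rate = 44100) {
  stopifnot(inherits(spec, "rhythmic_cue_spec"))
  check_freq(spec$carrier_freq, sample_rate)
  onsets <- (seq_len(spec$n_cycles) - 1) * spec$isi
  total <- onsets[spec$n_cycles] + spec$tone_duration
  x <- numeric(round(total * sample_rate))
  tone <- make_pure_tone(spec$carrier_freq, spec$tone_duration,
                         sample_rate, spec$ramp)
  nt <- length(tone$samples)
  for (on in onsets) {
    i0 <- round(on * sample_rate)
    idx <- (i0 + 1):(i0 + nt)
    x[idx] <- tone$samples
  }
  list(wave = waveform(x, sample_rate), onsets = onsets)
}

#' Synthesize the duration-matched continuous cue
#'
#' A single pure tone spanning the same interval as the rhythmic sequence,
#' including its inter-tone gaps. By default the tone ends at the last
#' rhythmic tone's offset, i.e. duration `(n_cycles - 1) * isi +
#' tone_duration`; set `full_cycles = TRUE` for the alternative convention of
#' `n_cycles * isi`.
#'
#' @param spec A [rhythmic_cue_spec()].
#' @param sample_rate Sampling rate in Hz.
#' @param full_cycles If `TRUE`, the tone spans `n_cycles` full periods.
#' @return A [waveform()].
#' @export
make_continuous_cue <- function(spec, sample_rate = 44100,
                                full_cycles = FALSE) {
  stopifnot(inherits(spec, "rhythmic_cue_spec"))
  dur <- if (full_cycles) spec$n_cycles * spec$isi
         else (spec$n_cycles - 1) * spec$isi + spec$tone_duration
  make_pure_tone(spec$carrier_freq, dur, sample_rate, spec$ramp)
}

#' Audio demo presets
#'
#' Named sweep-pair presets matching the supplementary audio demos: each demo
#' is an up sweep followed, after a short gap, by the matching down sweep.
#'
#' * `"S1"`: 40-ms sweeps, 5.5 to 7 kHz (above the phase-locking limit).
#' * `"S2"`: 10-ms sweeps, 0.5 to 2 kHz, 5-ms rise/decay.
#' * `"S3"`: 40-ms sweeps, 0.5 to 2 kHz.
#' * `"S4"`: 40-ms sweeps, 0.6 to 0.9 kHz.
#'
#' @param id One of `"S1"`, `"S2"`, `"S3"`, `"S4"`.
#' @param sample_rate Sampling rate in Hz.
#' @param gap Silent gap between the up and down sweep in seconds.
#' @return A list with `wave` (the concatenated [waveform()]), `up` and `down`
#'   (the individual sweeps) and `spec_up`, `spec_down`.
#' @export
audio_demo <- function(id = c("S1", "S2", "S3", "S4"), sample_rate = 44100,
                       gap = 0.5) {
  id <- match.arg(id)
  p <- switch(id,
    S1 = list(f1 = 5500, f2 = 7000, dur = 0.040, ramp = 0.005),
    S2 = list(f1 = 500,  f2 = 2000, dur = 0.010, ramp = 0.005),
    S3 = list(f1 = 500,  f2 = 2000, dur = 0.040, ramp = 0.005),
    S4 = list(f1 = 600,  f2 = 900,  dur = 0.040, ramp = 0.005))
  # 10-ms demo: 5-ms rise/decay fills the whole pulse
  if (id == "S2") p$ramp <- 0.005
  spec_up <- sweep_spec(p$f1, p$f2, p$dur, p$ramp)
  spec_down <- sweep_spec(p$f2, p$f1, p$dur, p$ramp)
  up <- make_linear_fm(spec_up, sample_rate)
  down <- make_linear_fm(spec_down, sample_rate)
  silence <- numeric(round(gap * sample_rate))
  list(wave = waveform(c(up$samples, silence, down$samples), sample_rate),
       up = up, down = down, spec_up = spec_up, spec_down = spec_down)
}
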