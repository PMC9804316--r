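#' @title Pipeline orchestration and figure reproduction
#' @name pipeline
#' @description
#' End-to-end convenience paths tying the modules together: a run
#' configuration whose defaults match the analyses' stated conditions (50
#' channels, 300-3000 Hz, 5-ms SACF decay, 40-ms targets, 50% duty cycle), a
#' one-call stimulus-to-pitch pipeline, and `reproduce()` helpers that
#' regenerate the figure/audio artifacts deterministically, each with a JSON
#' provenance record.
NULL

#' Default run configuration
#'
#' @param sample_rate Sampling rate in Hz.
#' @param n_channels,cf_low,cf_high Filterbank geometry.
#' @param decay_tau SACF memory time constant in seconds.
#' @param lag_max Largest SACF lag in seconds.
#' @param ihc_gain Linear input gain into the hair-cell stage.
#' @param criteria A [peak_criteria()].
#' @param seed Integer seed used by stochastic reproductions.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(sample_rate = 44100, n_channels = 50, cf_low = 300,
                       cf_high = 3000, decay_tau = 0.005, lag_max = 0.0125,
                       ihc_gain = 100, criteria = peak_criteria(),
                       seed = 1L) {
  stopifnot(inherits(criteria, "peak_criteria"))
  structure(list(sample_rate = sample_rate, n_channels = n_channels,
                 cf_low = cf_low, cf_high = cf_high, decay_tau = decay_tau,
                 lag_max = lag_max, ihc_gain = ihc_gain, criteria = criteria,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Built-in stimulus presets
#'
#' * `"jones_pair"`: 500-Hz standard + one-semitone-higher comparison,
#'   150-ms tones, 350-ms gap — the tone-pair pitch-discrimination stimulus.
#' * `"jones_standard"`: the 150-ms 500-Hz standard tone alone.
#' * `"lin_fm40"`: single 40-ms linear sweep, 500 to 2000 Hz.
#' * `"lin_fm40_down"`: its 2000 to 500 Hz reversal.
#' * `"lin_fm40_narrow"` / `"lin_fm40_narrow_down"`: 600 to 900 Hz band.
#' * `"lin_fm10"`: 10-ms 500 to 2000 Hz sweep (5-ms rise/decay).
#' * `"silence"`: 150 ms of silence.
#'
#' @param name Preset name.
#' @param sample_rate Sampling rate in Hz.
#' @return A [waveform()].
#' @export
stimulus_preset <- function(name, sample_rate = 44100) {
  switch(name,
    jones_pair = make_tone_pair(500, +1, 0.150, 0.350, sample_rate),
    jones_standard = make_pure_tone(500, 0.150, sample_rate),
    lin_fm40 = make_linear_fm(sweep_spec(500, 2000, 0.040), sample_rate),
    lin_fm40_down = make_linear_fm(sweep_spec(2000, 500, 0.040), sample_rate),
    lin_fm40_narrow = make_linear_fm(sweep_spec(600, 900, 0.040), sample_rate),
    lin_fm40_narrow_down =
      make_linear_fm(sweep_spec(900, 600, 0.040), sample_rate),
    lin_fm10 = make_linear_fm(sweep_spec(500, 2000, 0.010), sample_rate),
    silence = waveform(numeric(round(0.150 * sample_rate)), sample_rate),
    stop(sprintf("unknown stimulus preset '%s'", name)))
}

#' Run the full stimulus-to-pitch pipeline
#'
#' Synthesis (or a supplied waveform), gammatone filterbank, hair-cell
#' transduction, SACF at the evaluation time (default: stimulus offset) and
#' peak-based pitch estimation, in one call.
#'
#' @param stimulus A preset name (see [stimulus_preset()]) or a [waveform()].
#' @param cfg A [run_config()].
#' @param eval_time SACF evaluation time in seconds. The default reads the
#'   SACF at the stimulus offset minus the standard 5-ms decay ramp — the last
#'   moment of full stimulus power; inside the decay ramp the drive is already
#'   dying out and the reading is biased.
#' @param nonlinearity Optional exponent (2 or 3) applied after the hair-cell
#'   stage.
#' @return A list with `pitch` (a `"pitch_estimate"`), `sacf`, `haircell`,
#'   `filterbank` and `wave`.
#' @examples
#' \donttest{
#' out <- run_pipeline("jones_standard")
#' out$pitch
#' }
#' @export
run_pipeline <- function(stimulus, cfg = run_config(), eval_time = NULL,
                         nonlinearity = NULL) {
  w <- if (inherits(stimulus, "waveform")) stimulus
       else stimulus_preset(stimulus, cfg$sample_rate)
  if (is.null(eval_time)) {
    eval_time <- max(duration(w) - 0.005, duration(w) / 2)
  }
  # stimuli shorter than the lag axis get leading silence so the SACF can
  # span its full lag range (pre-stimulus history is silence)
  lead <- cfg$lag_max + 0.002 - eval_time
  if (lead > 0) {
    w <- waveform(c(numeric(round(lead * cfg$sample_rate)), w$samples),
                  cfg$sample_rate)
    eval_time <- eval_time + lead
  }
  fb <- design_filterbank(cfg$n_channels, cfg$cf_low, cfg$cf_high,
                          cfg$sample_rate)
  mcs <- apply_filterbank(w, fb)
  hc <- ihc_transduce(mcs, gain = cfg$ihc_gain)
  top <- if (!is.null(nonlinearity)) apply_nonlinearity(hc, nonlinearity)
         else hc
  s <- if (eval_time > cfg$lag_max) {
    sacf(top, eval_time, lag_max = cfg$lag_max, decay_tau = cfg$decay_tau)
  } else {
    stop("stimulus too short for the configured lag_max")
  }
  list(pitch = estimate_pitch(s, cfg$criteria), sacf = s, haircell = hc,
       filterbank = mcs, wave = w)
}

write_provenance <- function(dir, id, cfg, extra = list()) {
  rec <- c(list(artifact = id,
                package_version = as.character(utils::packageVersion("sacfpitch")),
                sample_rate = cfg$sample_rate, seed = cfg$seed),
           extra)
  jsonlite::write_json(rec, file.path(dir, paste0(id, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Reproduce a named figure or audio artifact
#'
#' Deterministically regenerates one of the package's analysis artifacts from
#' synthesis through analysis, writing CSV/WAV/PNG outputs plus a JSON
#' provenance record into `out_dir`.
#'
#' * `"fig1"`: overlap Monte Carlo, onset and full-on-period panels
#'   (per-run CSV, summary JSON, strip-plot PNG).
#' * `"fig2"`: SACF of the tone-pair standard vs. the 40-ms sweep
#'   (lag/amplitude CSVs, cochleagram + SACF PNG).
#' * `"fig3"`: envelope and fine structure of the mid-band channel response
#'   to up and down 40-ms sweeps (CSV, PNG).
#' * `"figS1"`: long-term magnitude/phase spectra of up vs. down sweeps.
#' * `"figS2"`: SACF and curvature for the 600-900 Hz sweep.
#' * `"videoS1"` / `"videoS2"`: running-SACF frames for the 40-ms sweep /
#'   tone stimuli (frame CSV; no video encoding).
#' * `"audioS1"`..`"audioS4"`: the sweep-pair audio demos as WAV files.
#'
#' @param figure_id Artifact id (see above).
#' @param cfg A [run_config()]; `cfg$seed` seeds stochastic artifacts.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
reproduce <- function(figure_id, cfg = run_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- switch(figure_id,
    fig1 = reproduce_fig1(cfg, out_dir),
    fig2 = reproduce_fig2(cfg, out_dir),
    fig3 = reproduce_fig3(cfg, out_dir),
    figS1 = reproduce_figS1(cfg, out_dir),
    figS2 = reproduce_figS2(cfg, out_dir),
    videoS1 = reproduce_video(cfg, out_dir, "lin_fm40", "videoS1"),
    videoS2 = reproduce_video(cfg, out_dir, "jones_standard", "videoS2"),
    audioS1 = reproduce_audio(cfg, out_dir, "S1"),
    audioS2 = reproduce_audio(cfg, out_dir, "S2"),
    audioS3 = reproduce_audio(cfg, out_dir, "S3"),
    audioS4 = reproduce_audio(cfg, out_dir, "S4"),
    stop(sprintf("unknown artifact id '%s'", figure_id)))
  invisible(files)
}

reproduce_fig1 <- function(cfg, out_dir) {
  set.seed(cfg$seed)
  onset <- simulate_overlap(overlap_config(isi = 0.6, mode = "onset"))
  full <- simulate_overlap(overlap_config(isi = 0.6, mode = "full_on_period"))
  df <- data.frame(
    run = rep(seq_along(onset$per_run_percent), 2),
    mode = rep(c("onset", "full_on_period"),
               each = length(onset$per_run_percent)),
    percent = c(onset$per_run_percent, full$per_run_percent))
  csv <- file.path(out_dir, "fig1_runs.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  summ <- file.path(out_dir, "fig1_summary.json")
  jsonlite::write_json(
    list(onset = list(mean_percent = onset$mean_percent,
                      max_percent = onset$max_percent,
                      analytic_percent = onset$analytic_percent),
         full_on_period = list(mean_percent = full$mean_percent,
                               max_percent = full$max_percent,
                               analytic_percent = full$analytic_percent)),
    summ, auto_unbox = TRUE, digits = NA)
  png <- file.path(out_dir, "fig1.png")
  grDevices::png(png, width = 700, height = 800)
  graphics::par(mfrow = c(2, 1))
  for (m in c("onset", "full_on_period")) {
    x <- df$percent[df$mode == m]
    graphics::plot(jitter(rep(1, length(x)), amount = 0.2), x,
                   pch = 16, cex = 0.3, col = grDevices::rgb(0, 0, 0, 0.15),
                   xlab = "", ylab = "% overlap trials per run",
                   xaxt = "n", main = paste("expectancy window:", m))
    graphics::abline(h = mean(x), col = "red")
  }
  grDevices::dev.off()
  write_provenance(out_dir, "fig1", cfg,
                   list(isi = 0.6, n_runs = 5000, n_trials_per_run = 100))
  c(csv, summ, png, file.path(out_dir, "fig1_provenance.json"))
}

sacf_to_df <- function(s) data.frame(lag = s$lags, amplitude = s$amplitude)

reproduce_fig2 <- function(cfg, out_dir) {
  tone <- run_pipeline("jones_standard", cfg)
  fm <- run_pipeline("lin_fm40", cfg)
  f1 <- file.path(out_dir, "fig2_sacf_tone.csv")
  f2 <- file.path(out_dir, "fig2_sacf_fm40.csv")
  utils::write.csv(sacf_to_df(tone$sacf), f1, row.names = FALSE)
  utils::write.csv(sacf_to_df(fm$sacf), f2, row.names = FALSE)
  png <- file.path(out_dir, "fig2.png")
  grDevices::png(png, width = 900, height = 700)
  graphics::par(mfrow = c(2, 2))
  cochleagram_panel(tone$filterbank, "filterbank: 150-ms 500-Hz tone")
  graphics::plot(tone$sacf$lags * 1000, tone$sacf$amplitude, type = "l",
                 xlab = "lag (ms)", ylab = "normalized SACF",
                 main = "tone: pitch peak near 2 ms")
  cochleagram_panel(fm$filterbank, "filterbank: 40-ms 0.5-2 kHz sweep")
  graphics::plot(fm$sacf$lags * 1000, fm$sacf$amplitude, type = "l",
                 xlab = "lag (ms)", ylab = "normalized SACF",
                 main = "sweep: no non-zero-lag peak")
  grDevices::dev.off()
  write_provenance(out_dir, "fig2", cfg,
                   list(tone_pitch_found = tone$pitch$found,
                        fm_pitch_found = fm$pitch$found))
  c(f1, f2, png, file.path(out_dir, "fig2_provenance.json"))
}

cochleagram_panel <- function(mcs, title) {
  n <- ncol(mcs$data)
  keep <- unique(round(seq(1, n, length.out = min(n, 2000))))
  img <- t(abs(mcs$data[, keep, drop = FALSE]))
  graphics::image(x = keep / mcs$sample_rate, y = seq_along(mcs$cfs), z = img,
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "time (s)", ylab = "channel", main = title)
}

reproduce_fig3 <- function(cfg, out_dir) {
  fs <- cfg$sample_rate
  fb <- design_filterbank(cfg$n_channels, cfg$cf_low, cfg$cf_high, fs)
  mid_cf <- sqrt(500 * 2000)
  ch <- which.min(abs(fb$cfs - mid_cf))
  up <- apply_filterbank(stimulus_preset("lin_fm40", fs), fb)
  dn <- apply_filterbank(stimulus_preset("lin_fm40_down", fs), fb)
  d_up <- decompose(up$data[ch, ], fb$cfs[ch], fs)
  d_dn <- decompose(dn$data[ch, ], fb$cfs[ch], fs)
  rep_ <- asymmetry_report(d_up, d_dn)
  t <- (seq_along(d_up$envelope) - 1) / fs
  df <- data.frame(time = t, up_env = d_up$envelope,
                   up_fs = d_up$fine_structure, down_env = d_dn$envelope,
                   down_fs = d_dn$fine_structure)
  csv <- file.path(out_dir, "fig3_channel.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  png <- file.path(out_dir, "fig3.png")
  grDevices::png(png, width = 700, height = 700)
  graphics::par(mfrow = c(2, 1))
  graphics::plot(t * 1000, d_up$fine_structure, type = "l", col = "gray",
                 xlab = "time (ms)", ylab = "amplitude",
                 main = sprintf("up sweep, CF %.0f Hz", fb$cfs[ch]))
  graphics::lines(t * 1000, d_up$envelope, col = "red")
  graphics::plot(t * 1000, d_dn$fine_structure, type = "l", col = "gray",
                 xlab = "time (ms)", ylab = "amplitude",
                 main = sprintf("down sweep, CF %.0f Hz", fb$cfs[ch]))
  graphics::lines(t * 1000, d_dn$envelope, col = "red")
  grDevices::dev.off()
  write_provenance(out_dir, "fig3", cfg,
                   list(channel_cf = fb$cfs[ch],
                        centroid_diff_s = rep_$diff$centroid))
  c(csv, png, file.path(out_dir, "fig3_provenance.json"))
}

reproduce_figS1 <- function(cfg, out_dir) {
  fs <- cfg$sample_rate
  up <- long_term_spectra(stimulus_preset("lin_fm40", fs))
  dn <- long_term_spectra(stimulus_preset("lin_fm40_down", fs))
  df <- data.frame(frequency = up$frequencies, up_mag = up$magnitude,
                   down_mag = dn$magnitude, up_phase = up$phase,
                   down_phase = dn$phase)
  csv <- file.path(out_dir, "figS1_spectra.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  png <- file.path(out_dir, "figS1.png")
  grDevices::png(png, width = 700, height = 700)
  graphics::par(mfrow = c(2, 1))
  band <- up$frequencies >= 200 & up$frequencies <= 4000
  graphics::matplot(up$frequencies[band],
                    cbind(up$magnitude[band], dn$magnitude[band]),
                    type = "l", lty = c(1, 2), col = c("red", "blue"),
                    xlab = "frequency (Hz)", ylab = "magnitude",
                    main = "amplitude spectra (identical)")
  graphics::matplot(up$frequencies[band],
                    cbind(up$phase[band], dn$phase[band]),
                    type = "l", lty = c(1, 2), col = c("red", "blue"),
                    xlab = "frequency (Hz)", ylab = "unwrapped phase (rad)",
                    main = "phase spectra (different)")
  grDevices::dev.off()
  write_provenance(out_dir, "figS1", cfg, list())
  c(csv, png, file.path(out_dir, "figS1_provenance.json"))
}

reproduce_figS2 <- function(cfg, out_dir) {
  out <- run_pipeline("lin_fm40_narrow", cfg)
  curv <- sacf_curvature(out$sacf)
  df <- sacf_to_df(out$sacf)
  df$curvature <- c(NA, curv$curvature, NA)
  csv <- file.path(out_dir, "figS2_sacf.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  png <- file.path(out_dir, "figS2.png")
  grDevices::png(png, width = 700, height = 500)
  graphics::plot(out$sacf$lags * 1000, out$sacf$amplitude, type = "l",
                 xlab = "lag (ms)", ylab = "normalized SACF",
                 main = "600-900 Hz sweep: curvature changes, no peak")
  grDevices::dev.off()
  write_provenance(out_dir, "figS2", cfg,
                   list(pitch_found = out$pitch$found,
                        n_sign_changes = length(curv$sign_change_lags)))
  c(csv, png, file.path(out_dir, "figS2_provenance.json"))
}

reproduce_video <- function(cfg, out_dir, preset, id) {
  w <- stimulus_preset(preset, cfg$sample_rate)
  fb <- design_filterbank(cfg$n_channels, cfg$cf_low, cfg$cf_high,
                          cfg$sample_rate)
  hc <- ihc_transduce(apply_filterbank(w, fb), gain = cfg$ihc_gain)
  frames <- seq(cfg$lag_max + 0.001, duration(w), by = 0.001)
  rs <- running_sacf(hc, frames, lag_max = cfg$lag_max,
                     decay_tau = cfg$decay_tau)
  df <- do.call(rbind, Map(function(s, t0)
    data.frame(frame_time = t0, lag = s$lags, amplitude = s$amplitude),
    rs, frames))
  csv <- file.path(out_dir, paste0(id, "_frames.csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  found <- vapply(rs, function(s)
    estimate_pitch(s, cfg$criteria)$found, logical(1))
  write_provenance(out_dir, id, cfg,
                   list(preset = preset, n_frames = length(frames),
                        any_pitch_found = any(found)))
  c(csv, file.path(out_dir, paste0(id, "_provenance.json")))
}

reproduce_audio <- function(cfg, out_dir, demo) {
  d <- audio_demo(demo, cfg$sample_rate)
  wav <- file.path(out_dir, paste0("audio", demo, ".wav"))
  write_wav(d$wave, wav)
  write_provenance(out_dir, paste0("audio", demo), cfg,
                   list(f_start = d$spec_up$f_start, f_end = d$spec_up$f_end,
                        duration = d$spec_up$duration))
  c(wav, file.path(out_dir, paste0("audio", demo, "_provenance.json")))
}
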