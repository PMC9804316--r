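#' @title Temporal-expectancy overlap Monte Carlo
#' @name overlap_mc
#' @description
#' When a rhythmic cue ends, it leaves behind a temporal expectancy: the
#' moments (or full on-periods) at which further cue tones would have
#' occurred. A target placed "at random" after the cue can land on those
#' expected positions. This module quantifies how often, by Monte Carlo
#' simulation and by an exact interval-union probability.
NULL

#' Overlap simulation configuration
#'
#' Geometry of the expectancy window and the random target placement.
#' Expected onsets continue the cue's period measured from the last cue
#' tone's onset, so (time measured from cue offset, for a cue with the given
#' duty cycle) the k-th expected onset falls at
#' `t_k = duty * isi + (k - 1) * isi`. In `"onset"` mode the k-th expectancy
#' window is the single instant `t_k`; in `"full_on_period"` mode it is the
#' interval `[t_k, t_k + duty * isi]`. The target onset is drawn uniformly on
#' `[0, window - target_duration]` so the target always fits inside the
#' placement window.
#'
#' @param isi Inter-stimulus interval of the cue in seconds (= 1/rate).
#' @param n_expected_cycles Number of expected post-cue cycles (default 4).
#' @param target_duration Target duration in seconds (default 0.040); must be
#'   below `isi`.
#' @param duty Cue duty cycle in (0, 1) (default 0.5).
#' @param mode `"onset"` or `"full_on_period"`.
#' @param window Target-onset placement window in seconds (default
#'   `n_expected_cycles * isi`); must be at least that long.
#' @param n_trials_per_run Trials per simulated run (default 100).
#' @param n_runs Number of runs (default 5000).
#' @return An object of class `"overlap_config"`.
#' @examples
#' cfg <- overlap_config(isi = 0.6)
#' expected_windows(cfg)
#' @export
overlap_config <- function(isi, n_expected_cycles = 4, target_duration = 0.040,
                           duty = 0.5, mode = c("onset", "full_on_period"),
                           window = n_expected_cycles * isi,
                           n_trials_per_run = 100, n_runs = 5000) {
  mode <- match.arg(mode)
  if (isi <= 0) stop("isi must be positive")
  if (target_duration >= isi) stop("target_duration must be below isi")
  if (duty <= 0 || duty >= 1) stop("duty must be in (0, 1)")
  if (n_expected_cycles < 0) stop("n_expected_cycles must be >= 0")
  if (window < n_expected_cycles * isi)
    stop("window must cover all expected cycles (>= n_expected_cycles * isi)")
  if (window <= target_duration)
    stop("window must exceed target_duration")
  if (n_trials_per_run < 1) stop("n_trials_per_run must be >= 1")
  if (n_runs < 1) stop("n_runs must be >= 1")
  structure(list(isi = isi, n_expected_cycles = as.integer(n_expected_cycles),
                 target_duration = target_duration, duty = duty, mode = mode,
                 window = window,
                 n_trials_per_run = as.integer(n_trials_per_run),
                 n_runs = as.integer(n_runs)),
            class = "overlap_config")
}

#' Expected temporal-expectancy windows
#'
#' @param c An [overlap_config()].
#' @return A two-column matrix (`start`, `end`) of expectancy windows in
#'   seconds after cue offset; in `"onset"` mode start equals end (instants).
#' @export
expected_windows <- function(c) {
  stopifnot(inherits(c, "overlap_config"))
  if (c$n_expected_cycles == 0L)
    return(matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))))
  k <- seq_len(c$n_expected_cycles)
  t_k <- c$duty * c$isi + (k - 1) * c$isi
  width <- if (c$mode == "onset") 0 else c$duty * c$isi
  cbind(start = t_k, end = t_k + width)
}

#' Exact overlap probability (interval-union oracle)
#'
#' A target `[onset, onset + target_duration]` intersects the expectancy
#' window `[s_k, e_k]` iff `onset` lies in `[s_k - target_duration, e_k]`.
#' The probability of overlap under a uniform onset on
#' `[0, window - target_duration]` is the Lebesgue measure of the union of
#' those favorable intervals, clipped to the placement range, divided by the
#' range length. Exact for any geometry, including overlapping favorable
#' intervals.
#'
#' @param c An [overlap_config()].
#' @return Overlap probability in `[0, 1]`.
#' @export
analytic_probability <- function(c) {
  stopifnot(inherits(c, "overlap_config"))
  win <- expected_windows(c)
  if (nrow(win) == 0L) return(0)
  range_len <- c$window - c$target_duration
  lo <- pmax(win[, "start"] - c$target_duration, 0)
  hi <- pmin(win[, "end"], range_len)
  ok <- hi > lo
  if (!any(ok)) return(0)
  iv <- cbind(lo[ok], hi[ok])[order(lo[ok]), , drop = FALSE]
  total <- 0; cur_lo <- iv[1, 1]; cur_hi <- iv[1, 2]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= cur_hi) {
      cur_hi <- max(cur_hi, iv[i, 2])
    } else {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- iv[i, 1]; cur_hi <- iv[i, 2]
    }
  }
  total <- total + (cur_hi - cur_lo)
  total / range_len
}

#' Simulate random-target overlap with the expectancy window
#'
#' Per trial, a target onset is drawn uniformly on
#' `[0, window - target_duration]`; the trial counts as an overlap when the
#' target interval intersects any expectancy window (closed intervals). Each
#' run's overlap percentage is `100 * overlaps / n_trials_per_run`.
#' Deterministic given the RNG state; set a seed before calling for
#' reproducibility.
#'
#' @param c An [overlap_config()].
#' @return An object of class `"overlap_result"`: `per_run_percent` (length
#'   `n_runs`), `mean_percent`, `max_percent`, `analytic_percent` (100 x the
#'   interval-union probability) and the `config`.
#' @examples
#' set.seed(1)
#' res <- simulate_overlap(overlap_config(isi = 0.6, n_runs = 200))
#' res$mean_percent
#' @export
simulate_overlap <- function(c) {
  stopifnot(inherits(c, "overlap_config"))
  win <- expected_windows(c)
  range_len <- c$window - c$target_duration
  n_tot <- c$n_runs * c$n_trials_per_run
  onsets <- stats::runif(n_tot, 0, range_len)
  hit <- rep(FALSE, n_tot)
  for (i in seq_len(nrow(win))) {
    hit <- hit | (onsets >= win[i, "start"] - c$target_duration &
                  onsets <= win[i, "end"])
  }
  per_run <- colMeans(matrix(hit, nrow = c$n_trials_per_run)) * 100
  structure(list(per_run_percent = per_run,
                 mean_percent = mean(per_run),
                 max_percent = max(per_run),
                 analytic_percent = 100 * analytic_probability(c),
                 config = c),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "<overlap> %s mode, isi %g ms: mean %.2f%%, max %.1f%% over %d runs (analytic %.2f%%)\n",
    x$config$mode, x$config$isi * 1000, x$mean_percent, x$max_percent,
    x$config$n_runs, x$analytic_percent))
  invisible(x)
}

#' Overlap statistics across cue rates
#'
#' Runs [simulate_overlap()] at each rate (ISI = 1/rate), holding the rest of
#' the configuration fixed. Faster cues pack the same number of expectancy
#' windows into a shorter span, so the overlap probability grows with rate.
#'
#' @param rates Cue rates in Hz.
#' @param base An [overlap_config()] providing every field except `isi` and
#'   `window` (which is reset to `n_expected_cycles * isi` per rate).
#' @return A data frame with one row per rate: `rate`, `isi`, `mean_percent`,
#'   `max_percent`, `analytic_percent`.
#' @export
rate_sweep <- function(rates, base) {
  stopifnot(inherits(base, "overlap_config"))
  if (!length(rates)) stop("rates must be non-empty")
  rows <- lapply(rates, function(r) {
    cfg <- overlap_config(isi = 1 / r,
                          n_expected_cycles = base$n_expected_cycles,
                          target_duration = base$target_duration,
                          duty = base$duty, mode = base$mode,
                          n_trials_per_run = base$n_trials_per_run,
                          n_runs = base$n_runs)
    res <- simulate_overlap(cfg)
    data.frame(rate = r, isi = cfg$isi, mean_percent = res$mean_percent,
               max_percent = res$max_percent,
               analytic_percent = res$analytic_percent)
  })
  do.call(rbind, rows)
}
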