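Package: sacfpitch
Title: Autocorrelation Pitch Extraction and Temporal-Expectancy Overlap Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two computational analyses in auditory psychophysics.
    A peripheral auditory model (gammatone filterbank, Meddis inner-hair-cell
    stage) feeds an exponentially weighted summary autocorrelation function
    (SACF) whose non-zero-lag peaks are pitch estimates; the pipeline shows
    that brief linear FM sweeps yield no autocorrelation pitch cue while pure
    tones and tone pairs do. A companion Monte Carlo module quantifies how
    often a uniformly timed target overlaps the temporal-expectancy window set
    by a rhythmic cue, with an exact interval-union oracle. Includes stimulus
    synthesis (tones, tone pairs, linear FM sweeps, rhythmic cue sequences),
    WAV import/export, envelope/fine-structure asymmetry analysis, and figure
    reproduction helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    jsonlite,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
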