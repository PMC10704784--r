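Package: duosync
Title: Dual-Site Spike and LFP Coupling Analysis for Simultaneous Brainstem Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying the coupling between two
    simultaneously recorded brain regions (locus coeruleus and
    trigeminocervical complex) from extracellular recordings: peri-stimulus
    time histograms with a tail-referenced evoked-bin criterion and
    component quantification, multi-timescale oscillation period estimation,
    FIR + Hilbert spike-phase histograms with preferred phase and
    precession, multi-unit delta-power synchronization indices, LFP
    decimation, spectrogram band-power time courses, sliding-window
    correlation and cross-correlogram lag estimation. Includes an
    inhomogeneous-Poisson synthetic-session generator with condition
    presets (naive, sensitized, propranolol) so that every stage is
    verifiable by parameter recovery, plus Lilliefors-gated two-group
    comparisons for condition contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    nortest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
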