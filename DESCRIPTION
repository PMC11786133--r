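Package: dfcrs
Title: Digital Frequency Customized Relieving Sound for Tinnitus Sound Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pitch-anchored customized sound therapy for chronic
    subjective tinnitus and for the analysis of two-arm longitudinal sound
    therapy trials. Computes the two 1/3-octave frequency bands flanking a
    matched tinnitus pitch, applies a dynamic +10 dB dual-band enhancement to
    music carriers via short-time Fourier analysis and overlap-add synthesis,
    and verifies the achieved band gains spectrally. Also scores the standard
    tinnitus assessment instruments (THI, HADS, AIS, FTQ, TCS, VAS), computes
    pure-tone averages and study eligibility from audiograms, generates
    synthetic two-arm four-timepoint cohorts with a known longitudinal and
    categorical-outcome structure, and fits the corresponding analysis models:
    random-intercept linear mixed models for the Tinnitus Handicap Inventory
    trajectory, stepwise multinomial logistic regression for the three-category
    treatment outcome, baseline group comparisons, and paired timepoint
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    jsonlite,
    yaml,
    lme4,
    lmerTest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
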