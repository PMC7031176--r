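Package: mousehrv
Title: Heart-Rate-Variability Analysis for Murine Telemetry ECG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing heart rate and heart-rate variability (HRV)
    from murine single-lead ECG or beat-interval (RR/NN) series. Provides
    R-peak detection and artifact cleaning, time-domain summaries (mean HR,
    SDNN, CV, Poincare SD1/SD2), Welch spectral band powers with
    temperature-adjusted VLF/LF/HF cut-offs that track the large heart-rate
    shift between standard laboratory temperature (20 C) and thermoneutrality
    (30 C), and non-linear indices (log-log spectral beta slope, multiscale
    sample entropy, detrended fluctuation analysis, rescaled-range Hurst
    exponent). A cohort layer assembles per-animal records into a
    2x2x2 age-by-temperature-by-autonomic-state design with paired
    basal-minus-intrinsic deltas, group summaries, the mean NN versus SDNN
    power law, and mixed-model contrasts. An integral pulse frequency
    modulation (IPFM) simulator with presets calibrated to published group
    means generates synthetic cohorts so the whole pipeline can be exercised
    without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    lme4
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
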