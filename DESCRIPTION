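Package: gravimea
Title: Multi-Electrode Array Electrophysiology Under Altered Gravity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable analysis pipeline for extracellular
    multi-electrode array (MEA) recordings of cultured neural networks exposed
    to gravity-phase protocols (drop-tower microgravity, centrifuge
    hypergravity). Includes a ground-truth synthetic recording generator
    (lognormal unit firing rates, burst-structured spike trains, biphasic
    waveforms, Gaussian and common-mode noise), zero-phase Butterworth
    high-pass filtering and common median referencing, MAD-threshold spike
    detection with per-channel PCA clustering and quality-based unit curation,
    five-parameter interval (MaxInterval) burst detection, gravity-phase
    segmentation with safety margins, unit-by-phase firing and burst rate
    tables, and the statistical battery used in gravity electrophysiology:
    repeated-measures one-way ANOVA with the Geisser-Greenhouse correction,
    Tukey multiple comparisons, Friedman test, ROUT outlier detection, and
    firing-rate density profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    matrixStats,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
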