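Package: voltrace
Title: Analysis of Fluorescence Voltage-Imaging Movies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of high-speed fluorescence voltage-imaging
    recordings of cultured neurons labelled with a fast voltage-sensitive dye.
    Provides movie input/output and denoising, conversion to percent dF/F0,
    single-neuron segmentation by principal and independent component analysis,
    action-potential detection with the nonlinear energy operator, spike
    waveform quantification (full width at half maximum, amplitude, rise and
    decay times), plateau-depolarization and burst/event classification,
    per-neuron firing statistics and group comparisons. A synthetic-movie
    generator with full ground truth (footprints, spike trains, kernel
    parameters) emulates the imaging regime of a 500 Hz sCMOS acquisition so
    every stage of the pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tiff,
    utils,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
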