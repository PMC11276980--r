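Package: epislice
Title: Epileptiform Activity Detection and Neuronal Feature Extraction for
    Slice Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying epileptiform activity in local field
    potential recordings from brain slices and for extracting membrane and
    synaptic features from patch-clamp recordings. Implements a
    percentile-threshold detector for unitary epileptiform events (zero-phase
    Butterworth prefiltering, amplitude-histogram thresholding, refractory
    lockout), segmentation of ictal discharges as dense event clusters,
    inter-event-interval statistics with bimodal mode estimation, Morlet
    wavelet spectrograms, passive membrane property estimation from current
    steps, action-potential waveform and firing-pattern metrics, evoked
    synaptic train measurements, and a robust modified z-score outlier
    screen. A seedable synthetic-data generator plants known ground truth
    (event times, cluster spans, membrane parameters, synaptic amplitudes) so
    every stage of the pipeline can be validated end to end without recorded
    data.
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
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    readr,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
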