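Package: songmf
Title: Multifractal Rhythm Analysis of Birdsong Amplitude Envelopes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies rhythmic expressiveness in birdsong from 1000 Hz
    amplitude envelopes. Provides multifractal detrended fluctuation
    analysis (generalized Hurst exponents over a q-grid and the multifractal
    spectrum width), significance testing against Iterative Amplitude
    Adjusted Fourier Transform (IAAFT) surrogate ensembles, note
    segmentation by differencing two Hodrick-Prescott filterings of the
    envelope, re-synthesis of "average-rhythm" songs from per-note-type mean
    envelope profiles and per-transition mean pause durations, per-note
    timing and intensity deviation series, and a synthetic-song generator
    with controllable deviation structure (jitter, drift, recurrent motifs)
    plus reference stochastic processes (white noise, fractional Gaussian
    noise, binomial cascades) with known scaling for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
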