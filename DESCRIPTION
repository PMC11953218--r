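Package: tepstates
Title: Microstate and Peak Analysis of TMS-Evoked Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing TMS-evoked EEG potentials (TEPs): component
    peak amplitude and latency extraction over predefined time and channel
    windows, global field power (GFP) utilities, a randomization test for
    topographic consistency, GFP-normalized modified k-means microstate
    segmentation with cross-validated selection of the number of maps,
    backfitting and microstate feature extraction (area under the curve,
    duration, onset), Mahalanobis-distance subject screening, and an
    inferential layer with repeated-measures ANOVA (Mauchly sphericity test,
    Greenhouse-Geisser correction, Tukey post-hocs), robust trimmed-means
    repeated-measures ANOVA, ANCOVA with stimulation intensity, and a
    gamma/identity mixed model for microstate onset order. A synthetic
    TEP generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    data.table,
    stats,
    utils,
    lme4,
    lmerTest,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    signal,
    optparse
Config/testthat/edition: 3
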