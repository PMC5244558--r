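Package: wormstates
Title: Postural State Analysis of C. elegans Eigenworm Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probabilistic binning of four-dimensional eigenworm posture time
    series into postural states with a shrinkage EM (FAB) Gaussian mixture that
    selects the number of states automatically, plus a K-means baseline.
    Quantifies per-strain postural state occurrence and transition divergences
    (Jensen-Shannon), screens strains for atypical transition patterns via
    standardized regression residuals with false-discovery-rate control, and
    dissects atypical strains with in-silico reference transformations
    (inactivity-bout removal and uniform acceleration) fitted to postural
    change speed distributions. Includes a synthetic strain-collection
    generator so the whole pipeline is testable without a behavioral database.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
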