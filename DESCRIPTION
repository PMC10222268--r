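Package: merpnet
Title: Multidomain Scalogram Fusion Networks for Event-Related Potential
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies event-related potentials (ERPs) from multichannel EEG
    by fusing frequency, time and spatial information. Computes analytic
    Morlet wavelet scalograms with their cone of influence (COI), derives the
    COI-modified Z- (zeroed outside the COI) and V- (in-COI coefficients
    only) scalograms, fuses channels into frequency-time-spatial cuboids and
    matrices, and classifies them with four small convolutional neural
    network models trained by backpropagation with the Adam optimizer.
    Includes m-subsample averaging of single trials, rank-of-rank-sum channel
    selection, within-subject (customized) and leave-one-subject-out
    (group-based) cross-validation drivers, and a synthetic multi-subject ERP
    simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
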