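Package: macroflim
Title: Label-Free Macrophage Phenotyping from Two-Photon FLIM Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phenotyping dermal macrophages from two-photon
    excited fluorescence lifetime imaging (TPE-FLIM). Simulates
    time-correlated single-photon counting (TCSPC) decay histograms and
    small FLIM image cubes for the dermal cell classes of a bundled
    reference table, fits bi-exponential decay models with instrument
    response function handling by Poisson maximum likelihood, derives the
    standard FLIM parameter set (tau1, tau2, taum, amplitude ratios) and
    first-harmonic phasor coordinates, and classifies M1/M2 macrophages
    against other dermal cells with an entropy-impurity decision tree,
    evaluated by repeated random 50/50 splits, one-vs-rest
    sensitivity/specificity, ROC curves and k-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart,
    pROC,
    optparse
Config/testthat/edition: 3
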