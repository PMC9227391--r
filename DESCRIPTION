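Package: nmrmix
Title: Compound Identification in 1H NMR Spectra of Mixtures with a
    Pseudo-Siamese Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens a library of pure-compound 1H NMR spectra against the
    spectrum of a mixture and reports which compounds the mixture contains.
    A two-branch (pseudo-Siamese) one-dimensional convolutional network is
    trained on spectral pairs synthesised by superposing randomly sampled
    library spectra at random ratios with additive noise, exploiting the
    additivity of NMR signals.  The package provides readers for Bruker
    processed-1D, JCAMP-DX and two-column text spectra, a Lorentzian
    multiplet simulator for fully synthetic libraries, the pair-augmentation
    and training machinery, database screening with probability thresholds,
    and an evaluation harness including a chemical-shift
    translation-invariance scan.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
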