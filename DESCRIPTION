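Package: dxlink
Title: Probabilistic Record Linkage of De-Identified Patient Data Using
    Diagnosis Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links patient records across two de-identified datasets using
    only binarized diagnosis codes. Implements a Bayesian matching model
    that turns per-code log-likelihood-ratio weights into directed posterior
    match probabilities with an explicit no-match category, together with
    its hyper-parameter estimation machinery (empirical code prevalences,
    a skew-t fit to the similarity distribution whose rightmost inflexion
    point yields the prior match probability, and discrepancy-rate
    estimation from high-similarity pairs). Also provides the classical
    Fellegi-Sunter latent-class comparator fitted by EM with blocking and a
    one-to-one largest-score variant, a simulator for sparse correlated
    binary code matrices with a correlated-Gaussian perturbation mechanism
    and known ground truth, and TPR/PPV evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    ludic
Config/testthat/edition: 3
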