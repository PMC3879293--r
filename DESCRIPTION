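Package: evicomb
Title: Evidence-Based Combining Classifiers for Uncertain Multi-View Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifier fusion under Dempster-Shafer evidence theory for
    multi-view classification problems with uncertain training labels, with
    applications to EEG brain-computer-interface signal analysis.  Crisp
    training labels are revised into crisp or soft (set-valued) labels by a
    confidence-relabeling procedure, one-hidden-layer neural experts trained
    per feature-space view approximate basic belief assignments, and
    Dempster's rule of combination followed by the pignistic transformation
    yields final decisions.  Includes belief-function algebra (mass, belief,
    plausibility, orthogonal sum, pignistic probabilities), a KNN-relabeling
    baseline, fixed-rule and decision-template combiners, diversity-driven
    forward selection of feature subspaces via inter-rater agreement, EEG
    feature extraction stages (surface Laplacian, Butterworth band-pass,
    epoching, Welch band power, one-versus-rest common spatial patterns), and
    synthetic-data generators for a three-class Gaussian triangle benchmark
    and band-limited oscillatory multichannel trials.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    nnet,
    jsonlite
Config/testthat/edition: 3
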