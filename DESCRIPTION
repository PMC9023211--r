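Package: reuploadr
Title: Data-Reuploading Variational Quantum Classification of Softmax Score Vectors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact statevector simulation of a small variational quantum
    classifier that re-uploads its input features at every layer. Provides the
    single- and two-qubit gate algebra (Hadamard, CNOT, axis rotations and the
    z-y-z Rot gate), a four-qubit six-layer data-reuploading ansatz with a
    Born-rule class readout, cross-entropy training with RMSProp using
    parameter-shift or finite-difference gradients, a softmax scoring
    front-end with CSV input and output, a Dirichlet generator of labelled
    score vectors emulating CNN softmax outputs, and confusion-matrix metrics
    with per-class one-vs-rest accuracy, precision, recall and F1. Intended
    for multi-class tumor score classification experiments where a
    convolutional network's softmax scores are handed to a small quantum
    circuit for the final decision.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    caret,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
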