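Package: latewave
Title: Analysis of Early and Late Report-Related Activity in Sensory Cortex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing rodent audiovisual change-detection
    experiments with laminar extracellular recordings: multi-alternative
    signal-detection and psychometric models of choice behaviour,
    kernel-based Poisson encoding models of single-neuron firing with
    raised-cosine temporal bases and elastic-net regularisation,
    ROC-based time-resolved discriminability with permutation tests and
    coding-onset estimation, pairwise noise-correlation dynamics, and
    random-forest population decoding.  Includes a synthetic-session
    generator that reproduces the trial structure, choice statistics and
    spiking phenomenology these analyses assume, with saved ground truth
    for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    ranger,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
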