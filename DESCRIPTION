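Package: coevdist
Title: Coevolution-Based Prediction of Inter-Residue Distances from
    Multiple Sequence Alignments
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts inter-residue distance maps for proteins from multiple
    sequence alignments. Computes direct-coupling-analysis feature tensors
    (covariance, shrunk precision, pseudolikelihood Potts couplings) and
    scalar coevolution statistics, assembles them into per-branch input
    stacks, and feeds them through four multi-task residual convolutional
    networks that jointly emit a real-value distance map and a 25-bin
    distogram. Includes ensembling, distance/contact/distogram conversions,
    top-L/k contact evaluation, distance-geometry restraint generation and
    violation scoring, a Potts-model synthetic-data simulator for end-to-end
    testing, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
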