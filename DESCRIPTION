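Package: phylopotts
Title: Phylogeny-Aware Correction of Potts Model Inference from Sequence Alignments
Version: 0.1.0
Authors@R:
    person("phylopotts", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Corrects phylogenetic bias in direct coupling analysis (DCA) of
    aligned sequence families. Single-site and pairwise stationary amino-acid
    frequencies are estimated by maximizing Felsenstein pruning likelihoods
    under independent-site and independent-pair evolution models on a given
    rooted tree; a de-biased alignment with the corrected statistics is
    rebuilt by simulated annealing and a Potts model is inferred from it by
    pseudo-likelihood maximization. Includes a controlled toy-model and
    tree-sampling simulator, mutation-rate estimation from Hamming-distance
    curves, and evaluation utilities (contact-prediction PPV, symmetrized
    Kullback-Leibler divergence, mutational-effect scoring).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    ape,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
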