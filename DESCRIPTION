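Package: phyloerr
Title: Maximum Likelihood Phylogeny Inference with Sequencing Error Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum likelihood phylogeny inference under the Kimura
    2-parameter substitution model with an explicit model of base-calling
    error in the tip likelihoods. A uniform miscall rate (epsilon), globally
    or per sequence, adjusts the conditional probabilities stored at the
    tips of the tree for every IUPAC nucleotide code, and the standard
    pruning (peeling) algorithm then propagates them to the root. Includes
    branch-length and topology optimization with or without a molecular
    clock, a simulation laboratory (clocklike branching-process trees, K2P
    sequence evolution, seeded miscall-error injection, Bernoulli SNP
    fixtures), Robinson-Foulds topology and branch-length tree comparison
    metrics, a replication harness for declared-versus-true error-rate
    experiments, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    Matrix,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
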