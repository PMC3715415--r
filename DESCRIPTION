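Package: cooccur3
Title: Triplet-Based Analysis of Disrupted Phylogenetic Co-Occurrence
Version: 0.1.0
Authors@R:
    person("cooccur3", "developers", email = "cooccur3@example.org",
           role = c("aut", "cre"))
Description: Tools to study why interacting proteins often fail to co-occur
    across genomes. Classifies pairs of phylogenetic profiles (matching,
    taxonomic subset, subset, other) using partial correlations of Dollo
    gain/loss reconstructions on a species tree, scores protein triplets with
    a complementarity score to detect shared subunits of two complexes,
    relates open/closed interaction triangles to the score via equal-count
    binning, quantifies how open triangles explain disrupted co-occurrence,
    and tests whether shared subunits are preferentially retained in
    duplicate. Includes a gene-content simulator (gain, loss, duplication on
    a species tree, planted shared-subunit complex architectures) with
    ground-truth labels for recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
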