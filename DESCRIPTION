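Package: rootphylo
Title: Outgroup-Free Rooting of Phylogenies with Nonreversible Substitution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood placement of the root of a phylogenetic tree
    on a fixed topology using nonreversible (UNREST-style) substitution
    models, without an outgroup. Provides rootstrap support (the proportion
    of nonparametric bootstrap replicates whose root falls on each branch of
    the ML tree), root-placement error metrics (rBED and rSED), an
    approximately unbiased (AU) confidence set of root branches computed by
    multiscale RELL bootstrap, site-wise and gene-wise log-likelihood
    diagnostics between competing root positions, matched-pairs symmetry
    tests for locus filtering, and a synthetic-data generator for rooted
    trees and alignments evolved under nonreversible models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape (>= 5.0),
    phytools,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    phangorn,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
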