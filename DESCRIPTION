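Package: introscan
Title: Phylo-HMM Genome Scans for Introgression under the Multispecies
    Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects genomic regions of introgressive descent from
    multi-genome alignments with a hidden Markov model whose states couple
    parental species trees (the trees displayed by a phylogenetic network
    with gene flow) with coalescent gene genealogies, so that introgression
    can be distinguished from incomplete lineage sorting. Provides
    multispecies-coalescent gene-tree topology probabilities by coalescent
    history enumeration, GTR emission likelihoods via Felsenstein pruning,
    log-space forward/backward/Viterbi decoding, maximum-likelihood training
    by coordinate ascent with Brent's method, network to MUL-tree
    conversion, region calling, and an isolation-with-migration coalescent
    simulator with recombination and per-site migration truth labels for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
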