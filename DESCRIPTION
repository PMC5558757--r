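Package: pastree
Title: Recognition of Poly(A) Signals in Genomic DNA with Omnivariate Decision Trees
Version: 0.1.0
Authors@R:
    person("pastree", "developers", email = "pastree@example.org", role = c("aut", "cre"))
Description: Discriminates functional poly(A) signal (PAS) hexamers from
    pseudo-PAS occurrences in 206-nt human genomic DNA windows. Implements a
    218-value sequence encoding (position-specific dinucleotide weight-matrix
    scores, positional information gain, DNA structural-profile window
    averages and compositional descriptors), an omnivariate decision tree
    whose internal nodes are heterogeneous classifiers (C4.5-style tree,
    neural network, random forest, ridge logistic regression) selected and
    pruned by a genetic algorithm, the stratified cross-validation protocol
    with a validation holdout and weak-variant data pooling, window extraction
    from genome FASTA plus polyA GTF annotations, and a synthetic sequence
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    glmnet,
    jsonlite,
    methods,
    parallel,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
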