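Package: GOnegatives
Title: Negative Example Selection for Gene Ontology Protein Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Selects reliable negative examples for protein function from
    positive-only Gene Ontology (GO) annotation data, a positive-unlabeled
    (PU) learning problem. Implements the co-annotation conditional
    probability ranking SNOB and its leaf-annotation predecessor ALBNeg, the
    topic-model ranking NETL (variational latent Dirichlet allocation over
    protein "documents" of GO-term "words", ranked by distributional overlap
    with the positive class), and the adapted PU baselines Rocchio, 1-DNF,
    the sibling heuristic, and a random sampler. Provides OBO and GAF/TSV
    parsers, true-path-rule annotation propagation (and its inverse for
    negatives), a temporal-holdout evaluation harness (false-negative
    curves, area ratios against the random baseline, equal-positives error
    rates, golden-set ROC via cross-validation with term masking), and a
    synthetic-data generator with planted mutually exclusive function
    modules for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
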