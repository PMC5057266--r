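Package: toxmodmine
Title: Co-Expression Module Mining for Toxicogenomic Injury Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for mining gene co-expression modules from
    toxicogenomic log-ratio matrices. Implements the Iterative Signature
    Algorithm (ISA) for bi-clustering with a multi-threshold sweep and merge,
    overlap-score clustering of modules into module clusters, phenotype
    activation scoring on Z-score standardized data, Fisher gene-set
    enrichment, random-forest injury-signature selection with out-of-bag
    evaluation, protein-protein interaction sub-network significance testing
    against two null models, and frequent co-expression statistics with
    shuffle-null and leave-out robustness controls. Ships a synthetic-data
    generator with planted bi-clusters, histopathology-style metadata and
    planted network structure so the whole workflow can be validated against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
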