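Package: hypomod
Title: Cell-Type Modules and Spatial Scoring for Hypothalamic Treatment Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a single-cell/single-nucleus analysis
    workflow linking hypothalamic cell types to an intracerebroventricular growth
    factor treatment: quality control and graph clustering of UMI count matrices,
    confidence-thresholded iterative label projection against reference atlases,
    pseudobulk negative-binomial Wald differential expression with a repeated
    downsampling DEG-distribution test, signed weighted co-expression module
    discovery (topological overlap, deterministic dendrogram cutting, eigengenes,
    kME, mixed-effects module-treatment association), principal-curve
    "pseudoventricle" spatial scoring with binned significance testing, and
    enrichment statistics (hypergeometric over-representation with a direction
    z-score, preranked GSEA, rank-rank hypergeometric overlap). A seeded
    synthetic-data module generates count matrices with the statistical structure
    the analysis assumes, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    igraph,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
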