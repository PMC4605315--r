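Package: eplink
Title: Predicting Enhancer-Promoter Interactions from Regulatory Genomics Signals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Supervised prediction of cell-line-specific enhancer-promoter
    interactions from one-dimensional regulatory genomics data (ChIP-seq,
    DNase I and RNA-seq). Regions and region pairs are encoded as peak-based
    feature vectors, labeled training sets are built from measured chromatin
    interactions with distance-matched negative sampling, and Random Forest
    classifiers are trained per cell line. A hybrid feature-selection
    procedure combines multi-task Group Lasso across cell lines with Random
    Forest permutation importance and a correlation-guided refinement step to
    find a minimal informative data-set panel. Cross-cell-line ensembles
    (percentile-rank averaging, Spectral Meta Learner, pooled training) score
    genome-wide candidate pairs; predicted networks are validated against
    independent interaction lists and binned contact matrices, and
    characterized by signal clustering, component taxonomy and gene-set
    enrichment. A synthetic-data generator with planted interaction rules
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    randomForest,
    glmnet,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
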