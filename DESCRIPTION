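Package: biafs
Title: Hybrid Filter and Clustering Feature Selection for Bioimpedance
    Body-Composition Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Feature selection for segmental bioelectrical impedance
    (BIA) tables: per-feature relevance scoring against a continuous
    body-composition target with the Hilbert-Schmidt Independence
    Criterion (HSIC) and a permutation-test confidence filter, followed
    by redundancy elimination with an improved Chameleon agglomerative
    clustering of the feature k-nearest-neighbour graph (relative
    interconnectivity and relative closeness merge criterion).  Includes
    the standard bioimpedance feature expansion (reciprocals, squares and
    pairwise products of segmental impedances), ordinary least-squares
    evaluation of selected feature sets, a synthetic cohort generator
    with known relevant, redundant and irrelevant structure, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    kernlab,
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
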