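Package: scprograms
Title: Robust Gene-Program Discovery, Scoring and Organoid Drug-Screen
    Statistics for Multi-Sample Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers robust consensus gene programs from multi-sample
    single-cell expression data by non-negative matrix factorization across a
    range of ranks, filters programs by cross-rank and cross-sample top-gene
    overlap, clusters them by Jaccard similarity (UPGMA) and extracts consensus
    signature genes. Scores every cell for each program against
    expression-matched background gene sets, annotates programs against curated
    meta-program references with permutation confidence thresholds and
    hypergeometric overlap tests, and projects datasets into a joint PCA space
    with correlation-driven component selection. Also provides organoid
    drug-screen statistics (viability normalization, z-scores, growth rates,
    median-effect fitting and the Chou-Talalay combination index) and a
    synthetic-data generator with planted co-expression programs and full
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    ape,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
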