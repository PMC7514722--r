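Package: DEFseq
Title: Entropy-Based Ranking of Differentially Expressed Genes from
    RNA-Seq Count Matrices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Distribution-free ranking of differentially expressed genes
    across two or more conditions, including time-course and multi-sample
    designs, from matrices of raw RNA-seq read counts. Counts are
    normalized with a generalized log counts-per-million transform whose
    scale exponent adapts to the largest library so that every normalized
    value is nonnegative, and each gene is scored with a differential
    entropy-like statistic H in [0, 1]: 0 for perfectly uniform expression
    across samples, approaching 1 as expression concentrates in a single
    sample. Genes are ranked by H and called differentially expressed
    above a cut-off. Includes a negative-binomial simulator with known
    differential-expression structure for evaluation, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: RNASeq, DifferentialExpression, Normalization, TimeCourse
RoxygenNote: 7.3.3
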