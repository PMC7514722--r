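# DEFseq

Distribution-free ranking of differentially expressed (DE) genes from
RNA-seq count matrices, across two or more conditions — including
time-course and multi-sample designs — and robust to zero counts and very
few replicates.

Parametric DE tools model counts with Poisson or negative-binomial
distributions and struggle when replicates are scarce or when a gene has
zero reads in one condition. DEFseq instead scores each gene with a
differential entropy-like function (DEF): a label-free, information-theoretic
measure of how unevenly a gene's normalized expression is spread across
samples. It is aimed at analysts who need a fast, assumption-light ranking
of genes by cross-sample variability — two-group comparisons, time courses,
or dozens of heterogeneous samples alike.

## The method

Given a gene × sample matrix of raw counts *y<sub>ij</sub>* with library
sizes *Y<sub>j</sub>* = Σ<sub>i</sub> *y<sub>ij</sub>*, counts are first
transformed with a **generalized log-cpm**:

    ỹ_ij = log2( (y_ij + 1) / (Y_j + 1) × 10^k ),   k = floor(log10(max_j Y_j)) + 1

The adaptive scale 10^k (instead of the fixed 10^6 of classic log-cpm)
makes every scaled proportion ≥ 1, hence every ỹ<sub>ij</sub> ≥ 0, with no
missing values even for zero counts or empty libraries.

Each gene *i* is then scored with the **differential entropy-like
function**: with proportions *p<sub>j</sub>* = ỹ<sub>ij</sub> / Σ<sub>j</sub> ỹ<sub>ij</sub>,

    H = 1 − [ −Σ_j p_j log p_j ] / log n

i.e. one minus the Shannon entropy of the profile relative to its maximum
log *n*. H ∈ [0, 1]: exactly 0 for perfectly uniform expression, exactly 1
when one sample carries all the expression, and independent of the log
base, sample order, and profile scale. For the profile (1, 2, 3), H =
0.079. Genes are ranked by H (rank 1 = largest) and called DE when H
strictly exceeds a cut-off — 0.05 by default, 0.01 as a permissive
alternative. No p-values are involved: H is a ranking score with a fixed
threshold, and condition labels are never consumed by the statistic.

## Worked example

Simulate a dataset with known structure (negative-binomial counts, 2
conditions × 2 replicates, 10% DE genes at fold change 8, plus
single-sample and all-zero genes), then run the full pipeline:

```r
library(DEFseq)
sim <- simulateCounts(m = 500, seed = 42)
res <- runDEF(sim, threshold = 0.05, verbose = TRUE)
#> genes in: 500
#> genes after all-zero filter: 475
#> normalization exponent k: 5
#> genes called DE at threshold 0.05: 26
head(as.data.frame(res[order(res$rank), ]), 5)
#>   gene_id def_value rank de_call
#> 1 gene114 0.2021523    1    TRUE
#> 2 gene405 0.1882747    2    TRUE
#> 3 gene482 0.1875508    3    TRUE
#> 4 gene355 0.1860640    4    TRUE
#> 5 gene329 0.1829928    5    TRUE
```

The log tells the story: 25 all-zero genes are filtered (nothing can be
said about them), the largest library fixes the normalization exponent
k = 5, and 26 of 475 genes exceed the 0.05 cut-off. Checking the ranking
against the simulation truth:

```r
ev <- evaluateRanking(sim, res, topN = 50)
round(ev$medianH, 4)
#>            de          null single_sample
#>        0.0145        0.0013        0.1521
ev$topFraction
#> [1] 0.5
```

Median H separates the classes as it should — genes expressed in a single
sample score highest, fold-change genes next, null genes near zero — and
half of the 50 true fold-change genes sit in the top 50 ranks (a random
ranking would place about 10% there).

The same workflow is available from a shell via the installed CLI
(`system.file("scripts", "def", package = "DEFseq")`), with subcommands
`run`, `normalize`, `simulate` and `evaluate`.

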