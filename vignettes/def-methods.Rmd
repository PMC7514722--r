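---
title: "Entropy-based ranking of differentially expressed genes: model and design notes"
author: "DEFseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based ranking of differentially expressed genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DEFseq)
library(SummarizedExperiment)
```

## The problem and the model

Differential-expression (DE) analysis of RNA-seq usually fits a count
distribution — Poisson or negative binomial — per gene and tests a
condition contrast. That works well with enough replicates, but degrades
when replicates are few, and fails outright on the patterns where a gene
has zero reads in every sample of one condition: there is nothing to
estimate a within-group variance from. DEFseq takes a different route: it
asks, per gene, *how unevenly is this gene's normalized expression spread
across the samples?* and ranks genes by that single number. No
distributional assumption, no condition labels, no p-values.

The score is a differential entropy-like function. For one gene with
nonnegative normalized values $\tilde y_1,\dots,\tilde y_n$ across $n \ge 2$
samples, let $p_j = \tilde y_j / \sum_j \tilde y_j$ and

$$H \;=\; 1 - \frac{-\sum_{j=1}^n p_j \log p_j}{\log n}.$$

The numerator is the Shannon entropy of the expression profile; dividing by
its maximum $\log n$ and subtracting from one gives a score in $[0, 1]$
that is 0 exactly for a uniform profile, 1 exactly when a single sample
carries all expression, and grows with concentration in between. The
log-ratio construction makes $H$ independent of the log base (we use the
natural log internally; base 2 or 10 give identical values to machine
precision), invariant under sample permutation, and invariant under
positive rescaling of the profile. For the profile $(1, 2, 3)$,
$H = 1 - [-(1/6)\log(1/6) - (2/6)\log(2/6) - (3/6)\log(3/6)]/\log 3 = 0.079$:

```{r}
defValue(c(1, 2, 3))
```

Because time points and tissues are just columns to the statistic, the same
score applies unchanged to two-group, multi-sample and time-course designs.

## Normalization: generalized log-cpm

$H$ needs nonnegative inputs, and raw counts need depth normalization. The
classic log-cpm, $\log_2((y + 0.5)/(Y_j + 1) \times 10^6)$, can be negative
for low counts (provided here as `logCPM()` for comparison, never fed to the
score by default). The package's working transform replaces the fixed
$10^6$ with an adaptive power of ten:

$$\tilde y_{ij} = \log_2\!\Big(\frac{y_{ij} + 1}{Y_j + 1} \times 10^k\Big),
\qquad k = \lfloor \log_{10}(\max_j Y_j) \rfloor + 1,$$

where $Y_j$ is the library size of sample $j$. The bracket is read as
floor, which makes $10^k$ the smallest power of ten strictly exceeding the
largest library — exactly what is needed for every scaled proportion to be
$\ge 1$ and every $\tilde y_{ij} \ge 0$. The $+1$ offsets keep the
proportion in $(0, 1]$ for zero counts and guard against empty libraries.
Equality $\tilde y_{ij} = 0$ is possible only for a zero count in a library
with $Y_j + 1 = 10^k$; the $0 \log 0 := 0$ convention keeps $H$ defined on
that boundary.

A consequence worth knowing: the normalized value of a zero count is
$\log_2(10^k/(Y_j+1))$, which depends on where $Y_j$ sits within its
power-of-ten decade. A gene with counts $(5, 0, 0, 0)$ therefore scores
differently in a 9-million-read library than in a 2-million-read one, even
at identical proportions. Published per-gene scores can only be reproduced
with the original library sizes, which is why this package's checks on such
patterns are ordering checks (concentrated beats spread) rather than
numeric ones.

## Parameters that matter

| Parameter | Where | Default | Why |
|---|---|---|---|
| `threshold` | `callDE()`, `runDEF()` | 0.05 | DE call is strict `H > threshold`; 0.01 is the customary permissive alternative. Lowering it can only add calls. |
| `k` | derived in `glogCPM()` | `floor(log10(max Y)) + 1` | Not user-settable: any smaller value breaks nonnegativity, any larger only shifts all values up. |
| `base` | `defValue()`, `defAll()` | natural log | Provably irrelevant to the result; exposed so the invariance is checkable. |
| `strict` | `readCounts()` | `TRUE` | The method is defined on integer read counts; `strict = FALSE` floors nonnegative reals from upstream quantifiers that emit expected counts. |

Design choices made where the design was genuinely open:

* **Ties and order.** Ranks use a stable sort: tied $H$ values keep input
  order, and gene/sample order is never changed on read, so identical
  inputs give byte-identical outputs.
* **Row-sum reading.** The profile total in the statistic is the per-gene
  sum of *normalized* values (the only reading consistent with the worked
  $(1,2,3)$ example, whose total is 6), not the library size used during
  normalization.
* **All-zero profiles.** Genes with zero counts everywhere are filtered
  before scoring (`filterAllZeroGenes()`); if an all-zero *normalized*
  profile still reaches the scorer it scores 0 (not DE) rather than erroring,
  keeping matrix-wide scoring total.
* **Strict call.** `de_call` uses `H > threshold`, not `>=`: a gene exactly
  at the cut-off is not called.

## Numerical conventions

* $0 \log 0 := 0$ inside profiles.
* $H$ is clamped to $[0, 1]$ and values below $10^{-12}$ are snapped to
  exact 0: a uniform profile of e.g. `rep(3.7, 5)` would otherwise score
  around $2 \times 10^{-16}$ from floating-point division. The snap is far
  below any biologically meaningful score (the working cut-offs are 0.05
  and 0.01).
* `computeK()` guards the floor against floating-point `log10`
  under-rounding at exact powers of ten, preserving $10^k > \max_j Y_j$.
* Scores are kept at full precision internally and printed with four
  decimals by `writeResults()`, matching the 3–4 significant figures at
  which the statistic is conventionally reported.
* A single sample is refused everywhere ($\log 1 = 0$ in the denominator);
  thresholds must lie strictly in $(0, 1)$.

## What the simulator emulates — and what it does not

`simulateCounts()` generates the study conditions used throughout the test
suite: negative-binomial counts (variance $\mu + \phi\mu^2$ — the model the
parametric competitors assume, hence the natural stress test for a
distribution-free score) over a conditions × replicates design, with four
truth classes: `null` genes at baseline mean everywhere; `de` genes
fold-changed in one randomly chosen non-baseline condition (direction
50/50 up or down; in time-course mode a monotone geometric mean trajectory
across conditions, mimicking smooth decay/rise patterns); `single_sample`
genes with a zero-truncated NB count in exactly one sample (truncation
guarantees the pattern that otherwise arises only stochastically); and
`all_zero` genes. Defaults — 1000 genes, 2 conditions × 2 replicates,
baseline mean 50, dispersion 0.1, 10% DE at fold 8, 5% single-sample, 5%
all-zero — represent a modestly sequenced two-group experiment with
technical replicates, the hardest published setting for parametric tools.

The simulator does **not** emulate real data's gene-specific mean-dispersion
trends, batch effects, gene length or GC bias, or correlated genes, and no
attempt is made to match any particular public dataset. Passing tests on it
demonstrate that the statistic recovers planted concentration structure
under NB noise — not that it matches any tool's behaviour on real tissue.

One genuine limitation surfaced by the simulator: like all CPM-family
normalizations, the transform is sensitive to composition. If a handful of
genes carry an enormous share of a library (e.g. a simulated fold change of
$10^6$), they *become* the library size, their own proportions flatten, and
unchanged genes appear variable. At realistic fold changes (up to ~32 in
the suite) the effect is negligible, but the score should not be trusted
when a few transcripts dominate sequencing depth.

## Problem sizes and evaluation

The test suite works at small scale by choice — profiles up to length 20,
matrices up to a few thousand genes, ten simulation seeds — which is ample
to pin down a scalar statistic and its invariants. `evaluateRanking()`
summarizes recovery on simulated data as the median $H$ per truth class and
the fraction of true `de` genes in the top $n_{de}$ ranks; under a random
ranking that fraction sits near the DE fraction (~0.1 at defaults), while
the pipeline at default conditions reaches ~0.5 with the remaining top slots
taken by `single_sample` genes — which are, by construction, genuinely
concentrated:

```{r}
sim <- simulateCounts(m = 500, seed = 42)
res <- runDEF(sim)
ev <- evaluateRanking(sim, res, topN = 50)
round(ev$medianH, 4)
ev$topFraction
```

## Known limitations

* $H$ is a ranking score, not a test statistic: there is no null
  distribution, p-value or FDR, and the 0.05/0.01 cut-offs are conventions,
  not error rates.
* The score measures concentration across *columns*; with many replicates
  per condition, a consistent two-group shift spreads over many columns and
  yields a smaller $H$ than the same shift concentrated in one sample.
  Condition labels are deliberately ignored.
* Scores depend on library sizes through the zero-count floor (see above),
  so $H$ values are comparable within a dataset, not across datasets.
* Composition sensitivity under extreme library imbalance, as described
  above.
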