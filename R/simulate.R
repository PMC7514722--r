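#' Simulate RNA-seq counts with known differential-expression structure
#'
#' Generates a gene x sample matrix of negative-binomial counts
#' (variance \eqn{\mu + \phi \mu^2}) for a design of
#' \code{nConditions x repsPerCondition} samples, with four gene classes of
#' known truth:
#' \describe{
#'   \item{null}{mean \code{nbMean} in every sample.}
#'   \item{de}{mean \code{nbMean} at baseline and \code{nbMean * foldChange}
#'     (or \code{/ foldChange}, direction 50/50) in one randomly chosen
#'     non-baseline condition; in time-course mode the mean instead follows
#'     a geometric (log-linear) trajectory across conditions from
#'     \code{nbMean} to the fold-changed level.}
#'   \item{single_sample}{a zero-truncated NB count in exactly one random
#'     sample and zero elsewhere -- the pattern of genes detected only
#'     through their concentration in one replicate.}
#'   \item{all_zero}{zero everywhere; removed by [filterAllZeroGenes()].}
#' }
#' The negative binomial is the standard generative model assumed by
#' parametric differential-expression tools, which makes it the natural
#' stress test for a distribution-free score. Class sizes are
#' \code{round(m * fraction)}; truth labels are stored in
#' \code{rowData(x)$truth}. The same seed reproduces the dataset exactly.
#'
#' @param m number of genes.
#' @param nConditions number of conditions (or time points), >= 2.
#' @param repsPerCondition replicates per condition, >= 1;
#'   \code{nConditions * repsPerCondition >= 2} samples in total.
#' @param deFraction,singleSampleFraction,zeroFraction fractions of genes in
#'   the \code{de}, \code{single_sample} and \code{all_zero} classes; their
#'   sum must be <= 1, the remainder is \code{null}.
#' @param foldChange between-condition fold change of \code{de} genes, > 1.
#' @param nbMean baseline expected count, > 0.
#' @param nbDispersion NB dispersion \eqn{\phi}, > 0.
#' @param timeCourse if TRUE, \code{de} genes follow a monotone geometric
#'   mean trajectory across conditions instead of a single-condition shift.
#' @param seed integer seed; fully determines the dataset.
#' @return a \linkS4class{DEFCountSet} with \code{rowData(x)$truth} labels,
#'   \code{colData(x)$condition}, and the configuration in
#'   \code{metadata(x)$simConfig}.
#' @examples
#' sim <- simulateCounts(m = 100, seed = 1)
#' table(rowData(sim)$truth)
#' @export
simulateCounts <- function(m = 1000, nConditions = 2, repsPerCondition = 2,
                           deFraction = 0.1, foldChange = 8,
                           nbMean = 50, nbDispersion = 0.1,
                           singleSampleFraction = 0.05,
                           zeroFraction = 0.05,
                           timeCourse = FALSE, seed = 1) {
    if (m < 1 || nConditions < 2 || repsPerCondition < 1)
        .defStop("defBadConfig",
                 "need m >= 1, nConditions >= 2, repsPerCondition >= 1")
    if (nConditions * repsPerCondition < 2)
        .defStop("defBadConfig", "need at least 2 samples in total")
    fr <- c(deFraction, singleSampleFraction, zeroFraction)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
        .defStop("defBadConfig",
                 "class fractions must lie in [0,1] and sum to at most 1")
    if (foldChange <= 1 || nbMean <= 0 || nbDispersion <= 0)
        .defStop("defBadConfig",
                 "need foldChange > 1, nbMean > 0, nbDispersion > 0")

    set.seed(as.integer(seed))
    n <- nConditions * repsPerCondition
    size <- 1 / nbDispersion
    condition <- rep(paste0("C", seq_len(nConditions)),
                     each = repsPerCondition)
    sampleIds <- paste0(condition, "R",
                        rep(seq_len(repsPerCondition), nConditions))
    geneIds <- sprintf("gene%0*d", nchar(m), seq_len(m))

    nDe <- round(m * deFraction)
    nSingle <- round(m * singleSampleFraction)
    nZero <- round(m * zeroFraction)
    truth <- rep("null", m)
    lab <- sample.int(m)
    truth[lab[seq_len(nDe)]] <- "de"
    truth[lab[nDe + seq_len(nSingle)]] <- "single_sample"
    truth[lab[nDe + nSingle + seq_len(nZero)]] <- "all_zero"

    cnt <- matrix(0L, m, n, dimnames = list(geneIds, sampleIds))
    isNull <- truth == "null"
    if (any(isNull))
        cnt[isNull, ] <- stats::rnbinom(sum(isNull) * n, mu = nbMean,
                                        size = size)
    for (i in which(truth == "de")) {
        up <- stats::runif(1) < 0.5
        r <- if (up) foldChange else 1 / foldChange
        if (timeCourse) {
            mus <- nbMean * r^((seq_len(nConditions) - 1) /
                               (nConditions - 1))
        } else {
            target <- if (nConditions == 2) 2L
                      else sample(2:nConditions, 1L)
            mus <- rep(nbMean, nConditions)
            mus[target] <- nbMean * r
        }
        cnt[i, ] <- stats::rnbinom(n, mu = rep(mus, each = repsPerCondition),
                                   size = size)
    }
    for (i in which(truth == "single_sample")) {
        j <- sample.int(n, 1L)
        cnt[i, j] <- .rztnbinom(1L, mu = nbMean, size = size)
    }

    x <- DEFCountSet(cnt, conditions = condition)
    rowData(x)$truth <- truth
    metadata(x)$simConfig <- list(
        m = m, nConditions = nConditions,
        repsPerCondition = repsPerCondition, deFraction = deFraction,
        foldChange = foldChange, nbMean = nbMean,
        nbDispersion = nbDispersion,
        singleSampleFraction = singleSampleFraction,
        zeroFraction = zeroFraction, timeCourse = timeCourse, seed = seed)
    x
}

# zero-truncated NB via inverse-cdf on (P(0), 1)
.rztnbinom <- function(nn, mu, size) {
    p0 <- stats::dnbinom(0, mu = mu, size = size)
    u <- stats::runif(nn, min = p0, max = 1)
    stats::qnbinom(u, mu = mu, size = size)
}

#' Evaluate a ranking against simulation truth
#'
#' Summarizes how well a result table recovers the known structure of a
#' simulated dataset: the median statistic per truth class, and the
#' fraction of true \code{de} genes found among the top ranks (by default
#' the top \eqn{n_{de}} ranks, where \eqn{n_{de}} is the number of true
#' \code{de} genes). Under a random ranking that fraction is about the DE
#' fraction of the genes scored.
#'
#' @param x a simulated \linkS4class{DEFCountSet} (with
#'   \code{rowData(x)$truth}).
#' @param results a result \code{DataFrame} from [runDEF()] or [callDE()]
#'   covering a subset of the simulated genes (those surviving the filter).
#' @param topN how many top ranks to inspect; default: the number of true
#'   \code{de} genes.
#' @return a list with \code{medianH} (named by truth class),
#'   \code{topFraction}, \code{nDe}, and \code{topN}.
#' @export
evaluateRanking <- function(x, results, topN = NULL) {
    stopifnot(is(x, "DEFCountSet"))
    truth <- rowData(x)$truth
    if (is.null(truth))
        .defStop("defBadConfig", "dataset carries no truth labels")
    names(truth) <- rownames(x)
    if (!all(results$gene_id %in% names(truth)))
        .defStop("defGeneMismatch",
                 "result table contains gene identifiers absent from the dataset")
    resTruth <- truth[results$gene_id]
    medianH <- vapply(split(results$def_value, resTruth),
                      stats::median, numeric(1))
    nDe <- sum(truth == "de")
    if (is.null(topN)) topN <- nDe
    top <- results$gene_id[results$rank <= topN]
    topFraction <- if (nDe == 0) NA_real_ else
        sum(truth[top] == "de") / nDe
    list(medianH = medianH, topFraction = topFraction,
         nDe = nDe, topN = as.integer(topN))
}
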