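#' Differential entropy-like statistic for one gene profile
#'
#' For a gene with nonnegative normalized values \eqn{\tilde y_1, \ldots,
#' \tilde y_n} across \eqn{n \ge 2} samples, form the proportions
#' \eqn{p_j = \tilde y_j / \sum_j \tilde y_j} and score
#' \deqn{H = 1 - \frac{-\sum_j p_j \log p_j}{\log n},}
#' i.e. one minus the Shannon entropy of the profile relative to its maximum
#' \eqn{\log n}. \eqn{H} lies in \eqn{[0, 1]}: exactly 0 for a perfectly
#' uniform profile, exactly 1 when a single sample carries all the
#' expression, and larger the more expression differs across samples. The
#' ratio of logarithms makes \eqn{H} independent of the log base, and the
#' statistic is invariant under sample permutation and positive rescaling of
#' the profile.
#'
#' Conventions: \eqn{0 \log 0 = 0} for zero entries, and an all-zero profile
#' (possible only for genes the all-zero filter would have removed) scores 0.
#'
#' @param values numeric vector of length >= 2, nonnegative normalized
#'   expression of one gene across samples.
#' @param base log base (default natural); the result is base-independent,
#'   the argument exists to make that checkable.
#' @return a single number in \eqn{[0, 1]}.
#' @examples
#' defValue(c(1, 2, 3))      # 0.0794: mild difference across 3 samples
#' defValue(c(1, 1, 1, 1))   # 0: perfectly uniform
#' defValue(c(7, 0, 0, 0))   # 1: all expression in one sample
#' @export
defValue <- function(values, base = exp(1)) {
    if (length(values) < 2L)
        .defStop("defSingleSample",
                 "the statistic is undefined for a single sample (log n = 0)")
    if (anyNA(values) || any(values < 0))
        .defStop("defNegativeValues",
                 "profile values must be nonnegative and non-missing")
    total <- sum(values)
    if (total == 0) return(0)
    p <- values[values > 0] / total
    ent <- -sum(p * log(p, base = base))
    h <- 1 - ent / log(length(values), base = base)
    h <- min(max(h, 0), 1)
    if (h < 1e-12) h <- 0   # snap fp residue so uniform profiles score 0
    h
}

#' Statistic for every gene of a normalized matrix
#'
#' Row-wise, vectorized application of [defValue()]; gene order is
#' preserved. Accepts the \linkS4class{DEFNormalized} produced by
#' [glogCPM()] or a plain nonnegative matrix.
#'
#' @param x a \linkS4class{DEFNormalized} or numeric matrix (genes x
#'   samples, >= 2 columns, rownames as gene identifiers).
#' @param base log base; the result does not depend on it.
#' @return named numeric vector of \eqn{H} values, one per gene.
#' @export
setGeneric("defAll", function(x, base = exp(1)) standardGeneric("defAll"))

.defAllMatrix <- function(x, base = exp(1)) {
    if (nrow(x) == 0L)
        return(stats::setNames(numeric(0), rownames(x)))
    if (ncol(x) < 2L)
        .defStop("defSingleSample",
                 "the statistic is undefined for a single sample (log n = 0)")
    if (anyNA(x) || any(x < 0))
        .defStop("defNegativeValues",
                 "normalized values must be nonnegative and non-missing")
    totals <- rowSums(x)
    p <- x / ifelse(totals > 0, totals, 1)
    plogp <- p * log(p, base = base)
    plogp[x == 0] <- 0          # 0 log 0 := 0
    ent <- -rowSums(plogp)
    h <- 1 - ent / log(ncol(x), base = base)
    h[totals == 0] <- 0         # all-zero profile: not differential
    h <- pmin(pmax(h, 0), 1)
    h[h < 1e-12] <- 0           # snap fp residue on uniform profiles
    stats::setNames(as.numeric(h), rownames(x))
}

#' @rdname defAll
#' @export
setMethod("defAll", "matrix", .defAllMatrix)

#' @rdname defAll
#' @export
setMethod("defAll", "DEFNormalized",
          function(x, base = exp(1)) .defAllMatrix(normValues(x), base))

#' Rank genes by their statistic
#'
#' Rank 1 is the largest \eqn{H}; ties keep input order (stable sort), so a
#' run is reproducible for any fixed input order.
#'
#' @param h named numeric vector of \eqn{H} values (names are gene
#'   identifiers).
#' @return a \code{DataFrame} with columns \code{gene_id},
#'   \code{def_value}, \code{rank}, in input order.
#' @export
rankGenes <- function(h) {
    h <- .asNamedH(h)
    rank <- integer(length(h))
    rank[order(h, decreasing = TRUE)] <- seq_along(h)
    DataFrame(gene_id = names(h), def_value = as.numeric(h), rank = rank)
}

.asNamedH <- function(h) {
    if (is.null(names(h)) && length(h) > 0L)
        names(h) <- paste0("gene", seq_along(h))
    h
}

#' Call differential expression at a cut-off
#'
#' A gene is called differentially expressed when its statistic strictly
#' exceeds the threshold. The cut-offs used in practice are 0.05 (default)
#' and the more permissive 0.01; lowering the threshold can only add calls.
#'
#' @param h named numeric vector of \eqn{H} values.
#' @param threshold cut-off in (0, 1); calls use strict \code{h > threshold}.
#' @return a \code{DataFrame} with columns \code{gene_id},
#'   \code{def_value}, \code{rank}, \code{de_call}; the threshold is stored
#'   in \code{metadata(x)$threshold}.
#' @examples
#' h <- c(gHigh = 0.0617, gLow = 0.0101)
#' callDE(h, 0.05)$de_call  # TRUE FALSE
#' callDE(h, 0.01)$de_call  # TRUE TRUE
#' @export
callDE <- function(h, threshold = 0.05) {
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        is.na(threshold) || threshold <= 0 || threshold >= 1)
        .defStop("defBadThreshold", "threshold must lie strictly in (0, 1)")
    res <- rankGenes(h)
    res$de_call <- res$def_value > threshold
    metadata(res)$threshold <- threshold
    res
}

#' Top-ranking genes
#'
#' @param h named numeric vector of \eqn{H} values.
#' @param k how many genes to return; if larger than the number of genes,
#'   all are returned.
#' @return character vector of the first \code{k} gene identifiers in rank
#'   order.
#' @export
topK <- function(h, k) {
    stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
    rt <- rankGenes(h)
    k <- min(as.integer(k), nrow(rt))
    rt$gene_id[order(rt$rank)][seq_len(k)]
}

#' Full differential-expression pipeline
#'
#' Filters all-zero genes, normalizes with the generalized log-cpm
#' transform, scores every gene with the entropy statistic, ranks, and calls
#' differential expression at the cut-off.
#'
#' @param x a \linkS4class{DEFCountSet} of raw counts.
#' @param threshold DE cut-off in (0, 1), default 0.05.
#' @param filter apply the all-zero-gene filter first (default TRUE).
#' @param verbose emit progress messages (gene counts, exponent k, number of
#'   calls).
#' @return a result \code{DataFrame} as from [callDE()], with
#'   \code{metadata} fields \code{threshold}, \code{k} and
#'   \code{removedGenes}.
#' @examples
#' sim <- simulateCounts(m = 200, seed = 7)
#' res <- runDEF(sim, threshold = 0.05)
#' head(res[order(res$rank), ])
#' @export
runDEF <- function(x, threshold = 0.05, filter = TRUE, verbose = FALSE) {
    stopifnot(is(x, "DEFCountSet"))
    if (verbose) message("genes in: ", nrow(x))
    if (filter) x <- filterAllZeroGenes(x)
    if (verbose) message("genes after all-zero filter: ", nrow(x))
    if (nrow(x) == 0L) {
        res <- callDE(stats::setNames(numeric(0), character(0)), threshold)
        metadata(res)$removedGenes <- removedGenes(x)
        return(res)
    }
    nm <- glogCPM(x)
    if (verbose) message("normalization exponent k: ", normExponent(nm))
    h <- defAll(nm)
    res <- callDE(h, threshold)
    metadata(res)$k <- normExponent(nm)
    metadata(res)$removedGenes <- removedGenes(x)
    if (verbose) message("genes called DE at threshold ", threshold, ": ",
                         sum(res$de_call))
    res
}
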