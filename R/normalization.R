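#' Per-sample library sizes
#'
#' The library size of sample \eqn{j} is the total number of mapped reads in
#' that sample, \eqn{Y_j = \sum_i y_{ij}} (the column sum of the count
#' matrix). A zero total is allowed; downstream the denominator is offset by
#' one so it never divides by zero.
#'
#' @param x a \linkS4class{DEFCountSet} or a numeric count matrix.
#' @return named numeric vector of column sums.
#' @export
setGeneric("librarySizes", function(x) standardGeneric("librarySizes"))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "DEFCountSet", function(x) colSums(counts(x)))

#' @rdname librarySizes
#' @export
setMethod("librarySizes", "matrix", function(x) colSums(x))

#' Adaptive scale exponent for generalized log-cpm
#'
#' \code{k = floor(log10(max_j Y_j)) + 1}: the smallest power-of-ten exponent
#' with \code{10^k} strictly greater than the largest library, hence
#' \code{10^k >= max_j Y_j + 1}. This guarantees that every scaled proportion
#' \code{(y + 1)/(Y_j + 1) * 10^k} is at least 1 and its log2 is nonnegative.
#' A guard bumps \code{k} if floating-point \code{log10} under-rounds at an
#' exact power of ten.
#'
#' @param x a \linkS4class{DEFCountSet}, a count matrix, or a numeric vector
#'   of library sizes.
#' @return a single positive integer.
#' @examples
#' computeK(c(4, 9))    # 1
#' computeK(c(100, 7))  # 3
#' @export
setGeneric("computeK", function(x) standardGeneric("computeK"))

.computeK <- function(totals) {
    maxY <- max(totals)
    if (!is.finite(maxY) || maxY <= 0)
        .defStop("defEmptyLibrary",
                 "empty library: all library sizes are zero")
    k <- as.integer(floor(log10(maxY)) + 1)
    if (10^k <= maxY) k <- k + 1L
    k
}

#' @rdname computeK
#' @export
setMethod("computeK", "numeric", function(x) .computeK(x))

#' @rdname computeK
#' @export
setMethod("computeK", "matrix", function(x) .computeK(colSums(x)))

#' @rdname computeK
#' @export
setMethod("computeK", "DEFCountSet",
          function(x) .computeK(librarySizes(x)))

#' Generalized log counts-per-million
#'
#' Transforms raw counts to
#' \deqn{\tilde y_{ij} = \log_2\!\left(\frac{y_{ij}+1}{Y_j+1} \times 10^k\right)}
#' with \eqn{Y_j} the library size of sample \eqn{j} and \eqn{k} from
#' [computeK()]. The +1 offsets keep the proportion inside \eqn{(0, 1]} even
#' for zero counts and empty libraries, and the adaptive \eqn{10^k} scale --
#' unlike the fixed \eqn{10^6} of classic log-cpm -- makes every transformed
#' value nonnegative, which the entropy statistic requires. Zero is attained
#' only for a zero count in a library with \eqn{Y_j + 1 = 10^k}.
#'
#' @param x a \linkS4class{DEFCountSet}.
#' @return a \linkS4class{DEFNormalized} with assay \code{"normalized"} and
#'   the exponent \code{k} recorded.
#' @examples
#' m <- matrix(c(10L, 90L, 90L, 10L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' nm <- glogCPM(DEFCountSet(m))
#' normValues(nm)
#' normExponent(nm)
#' @export
setGeneric("glogCPM", function(x) standardGeneric("glogCPM"))

#' @rdname glogCPM
#' @export
setMethod("glogCPM", "DEFCountSet", function(x) {
    y <- counts(x)
    Y <- colSums(y)
    k <- .computeK(Y)
    vals <- log2(sweep(y + 1, 2L, Y + 1, "/") * 10^k)
    # clip the -0/eps boundary: exact zero is the theoretical floor
    vals[vals < 0 & vals > -1e-12] <- 0
    se <- SummarizedExperiment(assays = list(normalized = vals),
                               colData = colData(x))
    new("DEFNormalized", se, k = k, method = "glog-cpm")
})

#' Classic log counts-per-million (voom-style)
#'
#' The conventional transform
#' \deqn{\bar y_{ij} = \log_2\!\left(\frac{y_{ij}+0.5}{Y_j+1} \times 10^6\right)}
#' provided for comparison only. Values can be negative for low counts,
#' which is why the entropy statistic is never computed from it by default.
#'
#' @param x a \linkS4class{DEFCountSet}.
#' @return a \linkS4class{DEFNormalized} (\code{method = "log-cpm"},
#'   \code{k = 6}).
#' @export
setGeneric("logCPM", function(x) standardGeneric("logCPM"))

#' @rdname logCPM
#' @export
setMethod("logCPM", "DEFCountSet", function(x) {
    y <- counts(x)
    Y <- colSums(y)
    vals <- log2(sweep(y + 0.5, 2L, Y + 1, "/") * 1e6)
    se <- SummarizedExperiment(assays = list(normalized = vals),
                               colData = colData(x))
    new("DEFNormalized", se, k = 6L, method = "log-cpm")
})
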