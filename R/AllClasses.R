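#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
NULL

#' DEFCountSet: a validated RNA-seq count container
#'
#' Thin extension of \linkS4class{SummarizedExperiment} holding a single
#' \code{"counts"} assay of raw, nonnegative integer read counts (genes in
#' rows, samples in columns), unique gene and sample identifiers, and an
#' optional per-sample \code{condition} column in \code{colData}. The entropy
#' statistic itself never consumes condition labels -- every column is treated
#' as a sample -- but they are carried for simulation evaluation and
#' reporting.
#'
#' At least two samples are required: the statistic divides a profile entropy
#' by \code{log(n)}, which vanishes for a single sample.
#'
#' @slot .. no additional slots; see \code{SummarizedExperiment}.
#' @seealso [DEFCountSet()] for construction, [readCounts()],
#'   [filterAllZeroGenes()], [glogCPM()]
#' @export
setClass("DEFCountSet", contains = "SummarizedExperiment")

.validDEFCountSet <- function(object) {
    msg <- NULL
    if (!("counts" %in% names(assays(object))))
        msg <- c(msg, "assay 'counts' is missing")
    else {
        x <- assay(object, "counts")
        if (anyNA(x))
            msg <- c(msg, "counts contain NA")
        else {
            if (any(x < 0))
                msg <- c(msg, "counts must be nonnegative")
            if (any(x != floor(x)))
                msg <- c(msg, "counts must be integers")
        }
    }
    if (ncol(object) < 2L)
        msg <- c(msg, "at least 2 samples are required (the statistic is undefined for a single sample)")
    if (is.null(rownames(object)) && nrow(object) > 0L)
        msg <- c(msg, "gene identifiers (rownames) are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be unique")
    if (is.null(colnames(object)))
        msg <- c(msg, "sample identifiers (colnames) are required")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be unique")
    if (is.null(msg)) TRUE else msg
}
setValidity("DEFCountSet", .validDEFCountSet)

#' Construct a DEFCountSet from a count matrix
#'
#' @param counts numeric matrix of nonnegative integer read counts with gene
#'   identifiers as rownames and sample identifiers as colnames.
#' @param conditions optional character vector of condition labels, one per
#'   sample (recycled into \code{colData(x)$condition}); may be named by
#'   sample identifier.
#' @return a \linkS4class{DEFCountSet}.
#' @examples
#' m <- matrix(c(5L, 0L, 0L, 0L, 4L, 8L, 6L, 2L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gA", "gB"), paste0("s", 1:4)))
#' DEFCountSet(m)
#' @export
DEFCountSet <- function(counts, conditions = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "numeric"
    cd <- DataFrame(row.names = colnames(counts))
    if (!is.null(conditions)) {
        if (!is.null(names(conditions)))
            conditions <- conditions[colnames(counts)]
        if (length(conditions) != ncol(counts))
            stop("'conditions' must supply one label per sample")
        cd$condition <- as.character(conditions)
    }
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("DEFCountSet", se)
}

#' DEFNormalized: normalized expression values
#'
#' A \linkS4class{SummarizedExperiment} extension holding log2-scale
#' normalized expression values together with the scale exponent \code{k}
#' that was used (the generalized log-cpm transform scales proportions by
#' \code{10^k}; the classic log-cpm uses the fixed \code{10^6}, i.e.
#' \code{k = 6}).
#'
#' @slot k integer scale exponent of the normalization.
#' @slot method character, \code{"glog-cpm"} or \code{"log-cpm"}.
#' @seealso [glogCPM()], [logCPM()], [defAll()]
#' @export
setClass("DEFNormalized",
    contains = "SummarizedExperiment",
    representation(k = "integer", method = "character"))

setValidity("DEFNormalized", function(object) {
    msg <- NULL
    if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
        msg <- c(msg, "'k' must be a single positive integer")
    if (length(object@method) != 1L ||
        !object@method %in% c("glog-cpm", "log-cpm"))
        msg <- c(msg, "'method' must be 'glog-cpm' or 'log-cpm'")
    if (!("normalized" %in% names(assays(object))))
        msg <- c(msg, "assay 'normalized' is missing")
    else if (identical(object@method, "glog-cpm") &&
             nrow(object) > 0L && any(assay(object, "normalized") < 0))
        msg <- c(msg, "generalized log-cpm values must be nonnegative")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn DEFCountSet-class raw count accessor.
#' @param object a \code{DEFCountSet}.
#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "DEFCountSet", function(object) assay(object, "counts"))

#' Normalized value accessors
#'
#' \code{normValues} returns the matrix of normalized values;
#' \code{normExponent} the scale exponent \code{k}; \code{normMethod} the
#' transform name.
#'
#' @param x a \linkS4class{DEFNormalized}.
#' @return matrix, integer, or character respectively.
#' @export
normValues <- function(x) {
    stopifnot(is(x, "DEFNormalized"))
    assay(x, "normalized")
}

#' @rdname normValues
#' @export
normExponent <- function(x) {
    stopifnot(is(x, "DEFNormalized"))
    x@k
}

#' @rdname normValues
#' @export
normMethod <- function(x) {
    stopifnot(is(x, "DEFNormalized"))
    x@method
}

setMethod("show", "DEFCountSet", function(object) {
    cat("DEFCountSet:", nrow(object), "genes x", ncol(object), "samples\n")
    if ("condition" %in% colnames(colData(object))) {
        tab <- table(colData(object)$condition)
        cat("conditions:",
            paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
    }
    if (!is.null(metadata(object)$removedGenes))
        cat("all-zero genes removed:",
            length(metadata(object)$removedGenes), "\n")
    invisible(NULL)
})

setMethod("show", "DEFNormalized", function(object) {
    cat("DEFNormalized (", object@method, ", k = ", object@k, "): ",
        nrow(object), " genes x ", ncol(object), " samples\n", sep = "")
    invisible(NULL)
})

# internal: named error constructor so callers can match on error class
.defStop <- function(class, msg) {
    stop(errorCondition(msg, class = c(class, "defError")))
}
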