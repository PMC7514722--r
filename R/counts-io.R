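#' Read a gene x sample count matrix from TSV/CSV
#'
#' Expects gene identifiers in the first column and sample identifiers in the
#' header row; every remaining cell must parse as a nonnegative integer read
#' count. Row and column order are preserved exactly as written, so ranks of
#' tied genes downstream are reproducible. The delimiter is auto-detected
#' from the file extension (\code{.csv} = comma, anything else = tab) unless
#' given explicitly.
#'
#' Errors carry distinct condition classes so callers can react
#' programmatically: \code{defMissingFile}, \code{defTooFewSamples},
#' \code{defDuplicateIds}, \code{defNegativeCounts},
#' \code{defNonIntegerCounts}.
#'
#' @param path path to a delimited text file.
#' @param delimiter \code{"auto"} (default), or an explicit field separator
#'   such as \code{"\t"} or \code{","}.
#' @param strict if \code{TRUE} (default) fractional counts are an error; if
#'   \code{FALSE}, nonnegative reals are floored to integers (some upstream
#'   quantifiers emit expected counts). Negative or non-numeric cells are
#'   always an error.
#' @param conditions optional path to a two-column, headerless or headered
#'   TSV mapping \code{sample_id} to \code{condition}, or a named character
#'   vector of labels.
#' @return a \linkS4class{DEFCountSet}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2\ts3\ts4", "ENSG00000164002\t5\t0\t0\t0"), tf)
#' readCounts(tf)
#' @export
readCounts <- function(path, delimiter = "auto", strict = TRUE,
                       conditions = NULL) {
    if (!file.exists(path))
        .defStop("defMissingFile", paste0("file not found: ", path))
    sep <- .resolveDelimiter(path, delimiter)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE,
                            colClasses = NA)
    if (ncol(df) < 3L)
        .defStop("defTooFewSamples",
                 "too few samples: need at least 2 sample columns")
    geneIds <- as.character(df[[1L]])
    sampleIds <- colnames(df)[-1L]
    if (anyDuplicated(geneIds))
        .defStop("defDuplicateIds", "duplicate gene identifiers in input")
    if (anyDuplicated(sampleIds))
        .defStop("defDuplicateIds", "duplicate sample identifiers in input")
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
        .defStop("defNonIntegerCounts",
                 "non-numeric cells in the count matrix")
    if (anyNA(vals))
        .defStop("defNonIntegerCounts", "missing values in the count matrix")
    if (any(vals < 0))
        .defStop("defNegativeCounts", "negative counts in input")
    if (any(vals != floor(vals))) {
        if (strict)
            .defStop("defNonIntegerCounts",
                     "fractional counts in input (use strict = FALSE to floor)")
        vals <- floor(vals)
    }
    dimnames(vals) <- list(geneIds, sampleIds)
    condVec <- .readConditions(conditions)
    DEFCountSet(vals, conditions = condVec)
}

.resolveDelimiter <- function(path, delimiter) {
    if (!identical(delimiter, "auto")) return(delimiter)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.readConditions <- function(conditions) {
    if (is.null(conditions)) return(NULL)
    if (is.character(conditions) && length(conditions) == 1L &&
        file.exists(conditions)) {
        df <- utils::read.table(conditions, header = FALSE, sep = "\t",
                                stringsAsFactors = FALSE)
        if (identical(tolower(df[1L, 1L]), "sample_id"))
            df <- df[-1L, , drop = FALSE]
        stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
    } else conditions
}

#' Write a count matrix to TSV/CSV
#'
#' Inverse of [readCounts()]: gene identifiers in the first column (header
#' \code{gene_id}), samples in the remaining columns, order preserved.
#'
#' @param x a \linkS4class{DEFCountSet}.
#' @param path output path; delimiter auto-detected from the extension
#'   unless \code{delimiter} is given.
#' @param delimiter \code{"auto"} or an explicit separator.
#' @return invisibly, \code{path}.
#' @export
writeCounts <- function(x, path, delimiter = "auto") {
    stopifnot(is(x, "DEFCountSet"))
    sep <- .resolveDelimiter(path, delimiter)
    df <- data.frame(gene_id = rownames(x), counts(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Remove genes with zero counts in every sample
#'
#' When every sample of a gene has zero reads nothing can be said about its
#' differential expression, so such genes are dropped before scoring. The
#' surviving genes keep their original order; the identifiers of the removed
#' genes are recorded in \code{metadata(x)$removedGenes} (see
#' [removedGenes()]). The operation is idempotent and partitions the input:
#' kept + removed = all genes.
#'
#' @param x a \linkS4class{DEFCountSet}.
#' @return a \code{DEFCountSet} containing only genes with at least one
#'   nonzero count.
#' @examples
#' m <- matrix(c(0L, 0L, 0L, 0L, 5L, 0L, 0L, 0L), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("gZero", "gOne"), paste0("s", 1:4)))
#' fx <- filterAllZeroGenes(DEFCountSet(m))
#' removedGenes(fx)
#' @export
filterAllZeroGenes <- function(x) {
    stopifnot(is(x, "DEFCountSet"))
    keep <- rowSums(counts(x) > 0) > 0
    removed <- rownames(x)[!keep]
    out <- x[keep, ]
    metadata(out)$removedGenes <-
        unique(c(metadata(x)$removedGenes, removed))
    out
}

#' @rdname filterAllZeroGenes
#' @return \code{removedGenes}: character vector of gene identifiers dropped
#'   by the all-zero filter (empty if the filter has not run or removed
#'   nothing).
#' @export
removedGenes <- function(x) {
    r <- metadata(x)$removedGenes
    if (is.null(r)) character(0) else r
}

#' Write / read a ranked result table
#'
#' The on-disk format is a TSV with columns \code{gene_id}, \code{def_value},
#' \code{rank}, \code{de_call}; \code{def_value} is printed with four decimal
#' places (matching the 3--4 significant figures reported for the statistic)
#' and \code{de_call} as lowercase \code{true}/\code{false}. Reading back a
#' written table reproduces it at the printed precision.
#'
#' @param results a result \code{DataFrame} as produced by [callDE()].
#' @param path output (or input) path.
#' @return \code{writeResults}: invisibly, \code{path}. \code{readResults}:
#'   a \code{DataFrame} with the four columns above.
#' @export
writeResults <- function(results, path) {
    stopifnot(all(c("gene_id", "def_value", "rank", "de_call") %in%
                  colnames(results)))
    df <- data.frame(
        gene_id = as.character(results$gene_id),
        def_value = sprintf("%.4f", results$def_value),
        rank = as.integer(results$rank),
        de_call = ifelse(results$de_call, "true", "false"),
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    if (!file.exists(path))
        .defStop("defMissingFile", paste0("file not found: ", path))
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE,
                            colClasses = c("character", "numeric",
                                           "integer", "character"))
    DataFrame(gene_id = df$gene_id,
              def_value = df$def_value,
              rank = df$rank,
              de_call = df$de_call == "true")
}
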