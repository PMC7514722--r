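# fixture builders shared across test files

# wrap a plain matrix as a DEFCountSet, inventing ids when absent
makeCounts <- function(mat, conditions = NULL) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat)))
        rownames(mat) <- paste0("g", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- paste0("s", seq_len(ncol(mat)))
    DEFCountSet(mat, conditions = conditions)
}

# random small count matrix (Poisson-ish, with zeros)
randomCountMatrix <- function(m, n, lambda = 20) {
    matrix(stats::rpois(m * n, lambda),
           nrow = m,
           dimnames = list(paste0("g", seq_len(m)),
                           paste0("s", seq_len(n))))
}

# write a count TSV fixture and return its path
writeCountFixture <- function(lines, ext = ".tsv") {
    path <- tempfile(fileext = ext)
    writeLines(lines, path)
    path
}

# independent scalar oracle for the statistic: literal transcription of the
# defining formula, kept free of any package vectorization
oracleH <- function(values, base = exp(1)) {
    p <- values / sum(values)
    terms <- ifelse(p > 0, p * log(p, base = base), 0)
    1 - (-sum(terms)) / log(length(values), base = base)
}
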