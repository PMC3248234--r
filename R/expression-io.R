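## Expression matrices travel as plain numeric matrices: genes in rows
## (unique rownames = gene ids), samples in columns (unique colnames).
## The on-disk dialect is tab-separated with a mandatory header line
## "gene_id\t<sample ids...>" and one row per gene.

#' Validate a genes-by-samples expression matrix
#'
#' Checks the structural invariants every analysis entry point relies on:
#' a numeric matrix with unique row (gene) and column (sample) names and
#' all values finite.  `minGenes`/`minSamples` default to the analysis
#' requirements (at least one other gene for a correlation vector; at
#' least two subgroups of two subjects).
#'
#' @param x numeric matrix, genes x samples, with dimnames.
#' @param minGenes,minSamples minimum admissible dimensions.
#' @param what label used in error messages.
#' @return `x`, invisibly, after validation.
#' @export
validateExpression <- function(x, minGenes = 2L, minSamples = 4L,
                               what = "expression matrix") {
    if (!is.matrix(x) || !is.numeric(x))
        stop(what, " must be a numeric matrix (genes x samples)")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop(what, " must carry gene ids as rownames and sample ids as colnames")
    if (anyDuplicated(rownames(x)))
        stop(what, ": duplicate gene ids")
    if (anyDuplicated(colnames(x)))
        stop(what, ": duplicate sample ids")
    if (!all(is.finite(x)))
        stop(what, " contains non-finite values (NA/NaN/Inf)")
    if (nrow(x) < minGenes)
        stop(what, sprintf(" must have at least %d genes", minGenes))
    if (ncol(x) < minSamples)
        stop(what, sprintf(" must have at least %d samples", minSamples))
    invisible(x)
}

## Coerce runGDAA-style input: matrix or SummarizedExperiment (first assay).
.asExpressionMatrix <- function(x, what = "expression matrix") {
    if (methods::is(x, "SummarizedExperiment")) {
        if (!requireNamespace("SummarizedExperiment", quietly = TRUE))
            stop("the SummarizedExperiment package is required to coerce ",
                 what)
        x <- SummarizedExperiment::assay(x, 1L)
        x <- as.matrix(x)
    }
    x
}

#' Read an expression matrix from a tab-separated file
#'
#' The first line must be a header starting with `gene_id` followed by the
#' sample identifiers; each subsequent line holds a gene identifier and one
#' numeric value per sample.  Malformed input (bad header, ragged rows,
#' non-numeric cells, duplicated identifiers) raises an error naming the
#' offending line.
#'
#' @param path path to a TSV file.
#' @return numeric matrix, genes x samples, with gene ids as rownames and
#'   sample ids as colnames.
#' @seealso [writeExpressionTsv()]
#' @export
readExpressionTsv <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    if (length(lines) < 2L)
        stop("expression file must contain a header and at least one gene row: ",
             path)
    header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
    if (length(header) < 2L || header[[1L]] != "gene_id")
        stop("malformed header on line 1: expected 'gene_id' followed by ",
             "sample identifiers")
    sampleIds <- header[-1L]
    if (anyDuplicated(sampleIds))
        stop("duplicate sample ids on line 1: ",
             paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
    n <- length(sampleIds)
    m <- length(lines) - 1L
    values <- matrix(NA_real_, nrow = m, ncol = n)
    geneIds <- character(m)
    for (i in seq_len(m)) {
        lineNo <- i + 1L
        fields <- strsplit(lines[[lineNo]], "\t", fixed = TRUE)[[1L]]
        if (length(fields) != n + 1L)
            stop(sprintf(
                "line %d: expected %d fields (gene id + %d values), found %d",
                lineNo, n + 1L, n, length(fields)))
        geneIds[i] <- fields[[1L]]
        vals <- suppressWarnings(as.numeric(fields[-1L]))
        if (anyNA(vals) || !all(is.finite(vals)))
            stop(sprintf("line %d: non-numeric or non-finite expression value",
                         lineNo))
        values[i, ] <- vals
    }
    dup <- which(duplicated(geneIds))
    if (length(dup))
        stop(sprintf("line %d: duplicate gene id '%s'",
                     dup[[1L]] + 1L, geneIds[dup[[1L]]]))
    dimnames(values) <- list(geneIds, sampleIds)
    validateExpression(values, minGenes = 1L, minSamples = 1L,
                       what = paste0("expression file ", path))
    values
}

## 17 significant digits round-trip an IEEE double exactly.
.fmtFloat <- function(x) sprintf("%.17g", x)

#' Write an expression matrix to a tab-separated file
#'
#' Values are serialized with 17 significant digits so a
#' write/read round trip reproduces the matrix bit-for-bit.
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [readExpressionTsv()]
#' @export
writeExpressionTsv <- function(x, path) {
    validateExpression(x, minGenes = 1L, minSamples = 1L)
    header <- paste(c("gene_id", colnames(x)), collapse = "\t")
    rows <- vapply(seq_len(nrow(x)), function(i) {
        paste(c(rownames(x)[i], .fmtFloat(x[i, ])), collapse = "\t")
    }, character(1))
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Write a GdaaResult as a tab-separated table
#'
#' Columns `gene_id`, `n_statistic`, `p_value`, `p_adjusted`, in input gene
#' order.  Floats use a fixed 17-significant-digit format, so identical
#' results serialize to byte-identical files - the basis of the
#' cross-configuration determinism checks.
#'
#' @param result a [GdaaResult-class] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(result, path) {
    stopifnot(is(result, "GdaaResult"))
    validObject(result)
    header <- "gene_id\tn_statistic\tp_value\tp_adjusted"
    rows <- paste(result@geneIds,
                  .fmtFloat(result@nStar),
                  .fmtFloat(result@pValue),
                  .fmtFloat(result@pAdjusted),
                  sep = "\t")
    writeLines(c(header, rows), path)
    invisible(path)
}

#' Read a results table written by [writeResultsTsv()]
#'
#' @param path path to the results TSV.
#' @return data.frame with columns gene_id, n_statistic, p_value,
#'   p_adjusted.
#' @export
readResultsTsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"),
                      check.names = FALSE)
}
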