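## Accessors and methods for GdaaResult.

#' Gene identifiers of a result
#' @param x a [GdaaResult-class].
#' @return character vector.
#' @export
geneIds <- function(x) x@geneIds

#' Observed N-statistics of a result
#' @param x a [GdaaResult-class].
#' @return numeric vector.
#' @export
nStar <- function(x) x@nStar

#' Permutation p-values of a result
#' @param x a [GdaaResult-class].
#' @return numeric vector.
#' @export
pValues <- function(x) x@pValue

#' PFER-adjusted p-values of a result
#' @param x a [GdaaResult-class].
#' @return numeric vector (p * m, uncapped).
#' @export
pAdjusted <- function(x) x@pAdjusted

#' @describeIn GdaaResult-class coerce to a data.frame with columns
#'   gene_id, n_statistic, p_value, p_adjusted (input gene order).
#' @param x a GdaaResult.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "GdaaResult", function(x, ...) {
    data.frame(gene_id = x@geneIds, n_statistic = x@nStar,
               p_value = x@pValue, p_adjusted = x@pAdjusted,
               stringsAsFactors = FALSE)
})

#' Rank genes by evidence of differential association
#'
#' Orders genes by ascending p-value, breaking ties by descending
#' N-statistic (stronger observed separation first), then by input order.
#'
#' @param x a [GdaaResult-class].
#' @return integer permutation of 1..m (gene indices, most significant
#'   first).
#' @export
rankGenes <- function(x) {
    order(x@pValue, -x@nStar, seq_along(x@geneIds))
}

setMethod("show", "GdaaResult", function(object) {
    m <- length(object@geneIds)
    cat(sprintf(
        "GdaaResult: %d genes, K = %d permutations, G = %d subgroups, seed = %d\n",
        m, object@K, object@G, object@seed))
    cat(sprintf("  p-value grid: multiples of 1/%d; adjusted = p * %d (PFER, uncapped)\n",
                object@K, m))
    top <- head(rankGenes(object), 5L)
    cat("  top genes:\n")
    for (i in top)
        cat(sprintf("    %-12s N* = %.4g  p = %.4g  p.adj = %.4g\n",
                    object@geneIds[i], object@nStar[i], object@pValue[i],
                    object@pAdjusted[i]))
    invisible(object)
})

setMethod("show", "SubgroupPartition", function(object) {
    cat(sprintf("SubgroupPartition: %d subgroups over %d samples (sizes: %s)\n",
                length(object@subgroups), sum(lengths(object@subgroups)),
                paste(lengths(object@subgroups), collapse = ", ")))
    invisible(object)
})

setMethod("show", "PermutationPlan", function(object) {
    cat(sprintf("PermutationPlan: K = %d permutations of %d pooled samples (seed %d)\n",
                object@K, object@nTotal, object@seed))
    invisible(object)
})

setMethod("show", "NullDistribution", function(object) {
    cat(sprintf("NullDistribution: %d permutations x %d genes\n",
                nrow(object@stats), ncol(object@stats)))
    invisible(object)
})

setMethod("show", "ExecutorConfig", function(object) {
    cat(sprintf("ExecutorConfig: %d worker(s) x %d lane(s)%s\n",
                object@nWorkers, object@lanes,
                if (is.na(object@maxInFlight)) ""
                else sprintf(", max %d in flight", object@maxInFlight)))
    invisible(object)
})

#' Null-distribution matrix accessor
#' @param x a [NullDistribution-class].
#' @return K x m numeric matrix.
#' @export
nullStats <- function(x) x@stats
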