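#' @import methods
NULL

## Tolerance below which an energy statistic is allowed to dip under zero
## (pure floating-point roundoff; the statistic is nonnegative in exact
## arithmetic).
.N_STAT_NEG_TOL <- 1e-9

#' SubgroupPartition: disjoint subject subgroups within one condition
#'
#' An ordered list of `G` disjoint index sets over the samples of one
#' condition.  Correlation vectors are estimated once per subgroup, giving a
#' sample of `G` correlation vectors per gene per condition.  Every subgroup
#' must contain at least two subjects (a Pearson correlation needs two
#' points) and sizes may differ by at most one, so the partition is as
#' balanced as the sample count allows.
#'
#' @slot subgroups list of integer vectors, 1-based sample indices.
#' @seealso [partitionSubgroups()]
#' @export
setClass("SubgroupPartition", representation(subgroups = "list"))

setValidity("SubgroupPartition", function(object) {
    sg <- object@subgroups
    if (length(sg) < 1L)
        return("partition must contain at least one subgroup")
    if (!all(vapply(sg, is.integer, logical(1))))
        return("subgroups must be integer vectors")
    idx <- unlist(sg, use.names = FALSE)
    n <- length(idx)
    if (!identical(sort(idx), seq_len(n)))
        return("subgroups must be disjoint and cover 1..n exactly")
    sizes <- lengths(sg)
    if (any(sizes < 2L))
        return("every subgroup must contain at least two subjects")
    if (max(sizes) - min(sizes) > 1L)
        return("subgroup sizes must differ by at most 1")
    TRUE
})

#' SubgroupMoments: per-gene, per-subgroup sums and sums of squares
#'
#' Read-shared moment arrays used to assemble Pearson correlations from
#' cross-products: entry (i, j) of `sums` is the sum of gene i's expression
#' over the subjects of subgroup j; `sumsSq` holds the matching sums of
#' squares.  Both are computed once per (permutation, condition) and treated
#' as read-only thereafter.
#'
#' @slot sums m x G numeric matrix of within-subgroup sums.
#' @slot sumsSq m x G numeric matrix of within-subgroup sums of squares.
#' @slot sizes integer vector of subgroup sizes (length G).
#' @seealso [computeSubgroupMoments()]
#' @export
setClass("SubgroupMoments",
         representation(sums = "matrix", sumsSq = "matrix",
                        sizes = "integer"))

setValidity("SubgroupMoments", function(object) {
    if (!identical(dim(object@sums), dim(object@sumsSq)))
        return("sums and sumsSq must have identical dimensions")
    if (ncol(object@sums) != length(object@sizes))
        return("one size per subgroup required")
    ## Cauchy-Schwarz: n * sum(x^2) >= (sum x)^2, up to roundoff
    lhs <- sweep(object@sumsSq, 2, object@sizes, `*`)
    slack <- 1e-8 * pmax(abs(lhs), 1)
    if (any(lhs - object@sums^2 < -slack))
        return("sums of squares violate the Cauchy-Schwarz bound")
    TRUE
})

#' CorrelationSample: Fisher-transformed correlation matrices per subgroup
#'
#' For one condition, a list of `G` symmetric m x m matrices; entry
#' `w[[k]][i, j]` is the Fisher z-transform of the Pearson correlation
#' between genes i and j estimated within subgroup k.  Row i of `w[[k]]`
#' (entry i excluded) is gene i's correlation vector from subgroup k.  The
#' diagonal is fixed at 0 so that full-row Euclidean distances equal
#' distances between the entry-i-excluded vectors exactly.
#'
#' @slot w list of m x m numeric matrices, one per subgroup.
#' @seealso [correlationSample()]
#' @export
setClass("CorrelationSample", representation(w = "list"))

setValidity("CorrelationSample", function(object) {
    for (k in seq_along(object@w)) {
        wk <- object@w[[k]]
        if (!is.matrix(wk) || nrow(wk) != ncol(wk))
            return("each subgroup matrix must be square")
        if (!all(is.finite(wk)))
            return("all transformed correlations must be finite")
        if (any(diag(wk) != 0))
            return("diagonal must be exactly zero")
        if (!identical(wk, t(wk)))
            return("each subgroup matrix must be symmetric")
    }
    TRUE
})

#' PermutationPlan: seeded, centrally generated permutation indices
#'
#' K permutations of the pooled 2n subjects, drawn once from R's
#' Mersenne-Twister generator ("Rejection" sampling kind) seeded with
#' `seed`.  Workers receive index vectors from the plan and never draw
#' random numbers themselves, which is what makes results independent of
#' the parallel configuration.
#'
#' @slot seed integer seed used to generate the plan.
#' @slot K number of permutations.
#' @slot nTotal pooled sample count (2n).
#' @slot perms K x nTotal integer matrix; each row is a permutation of
#'   1..nTotal.
#' @seealso [makePermutationPlan()]
#' @export
setClass("PermutationPlan",
         representation(seed = "integer", K = "integer", nTotal = "integer",
                        perms = "matrix"))

setValidity("PermutationPlan", function(object) {
    if (object@K < 1L) return("K must be >= 1")
    if (nrow(object@perms) != object@K)
        return("plan must hold exactly K permutations")
    if (ncol(object@perms) != object@nTotal)
        return("each permutation must cover all pooled samples")
    ref <- seq_len(object@nTotal)
    for (k in seq_len(object@K))
        if (!identical(sort(object@perms[k, ]), ref))
            return(sprintf("row %d is not a permutation of 1..%d",
                           k, object@nTotal))
    TRUE
})

#' NullDistribution: permutation N-statistics
#'
#' A K x m matrix whose row k holds the per-gene N-statistics recomputed
#' under the k-th permutation of the pooled subjects.  Column i is the
#' permutation null sample for gene i.
#'
#' @slot stats K x m numeric matrix of permutation N-statistics.
#' @seealso [computeNull()], [permutationPValues()]
#' @export
setClass("NullDistribution", representation(stats = "matrix"))

setValidity("NullDistribution", function(object) {
    s <- object@stats
    if (!all(is.finite(s))) return("all permutation statistics must be finite")
    if (any(s < -.N_STAT_NEG_TOL))
        return("permutation N-statistics must be nonnegative up to roundoff")
    TRUE
})

#' ExecutorConfig: two-tier parallel execution shape
#'
#' Coarse grain: `nWorkers` worker processes each pull one not-yet-assigned
#' permutation at a time from the plan.  Fine grain: within a worker the m
#' genes are split into `lanes` contiguous blocks; each lane computes and
#' writes only its own block of the per-permutation statistic vector while
#' sharing one logical copy of the permuted data and moment arrays.  All
#' configurations produce byte-identical results.
#'
#' @slot nWorkers number of permutation-level worker processes (>= 1).
#' @slot lanes number of gene-block lanes per worker (>= 1).
#' @slot maxInFlight optional cap on simultaneously dispatched
#'   permutations (NA = no cap beyond `nWorkers`).
#' @seealso [executorConfig()], [dispatch()]
#' @export
setClass("ExecutorConfig",
         representation(nWorkers = "integer", lanes = "integer",
                        maxInFlight = "integer"))

setValidity("ExecutorConfig", function(object) {
    if (object@nWorkers < 1L) return("nWorkers must be >= 1")
    if (object@lanes < 1L) return("lanes must be >= 1")
    if (!is.na(object@maxInFlight) && object@maxInFlight < 1L)
        return("maxInFlight must be >= 1 when set")
    TRUE
})

#' SimulationConfig: parameters of the planted-block generator
#'
#' Describes a two-condition synthetic dataset: m genes by n samples per
#' condition, with `daGenes` genes forming an equicorrelated block whose
#' within-block correlation is `rhoA` in condition A and `rhoB` in
#' condition B; all remaining genes are independent.  The block is built by
#' the Gaussian factor construction x = sqrt(rho) f + sqrt(1 - rho) sigma e,
#' which requires rho in [0, 1).
#'
#' @slot m gene count.
#' @slot n samples per condition.
#' @slot daGenes number of planted differentially associated genes.
#' @slot rhoA,rhoB within-block correlation under each condition.
#' @slot noiseSd residual standard deviation (sigma above; 1 gives a
#'   within-block correlation of exactly rho).
#' @slot seed integer seed.
#' @seealso [simulationConfig()], [generateDaPair()]
#' @export
setClass("SimulationConfig",
         representation(m = "integer", n = "integer", daGenes = "integer",
                        rhoA = "numeric", rhoB = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@m < 2L) return("m must be >= 2")
    if (object@n < 4L) return("n must be >= 4")
    if (object@daGenes < 0L || object@daGenes > object@m)
        return("daGenes must lie in [0, m]")
    for (rho in c(object@rhoA, object@rhoB)) {
        if (rho < 0 || rho >= 1)
            return("the factor construction requires rho in [0, 1)")
        if (object@daGenes > 1L && rho < -1 / (object@daGenes - 1))
            return("equicorrelation block is not positive definite")
    }
    if (object@noiseSd <= 0) return("noiseSd must be positive")
    TRUE
})

#' GdaaResult: per-gene differential-association test results
#'
#' Observed N-statistics, permutation p-values and PFER-adjusted p-values
#' for every gene, in input gene order.  p-values live on the grid
#' \{0, 1/K, ..., 1\}; adjusted p-values are p * m, deliberately uncapped
#' (they bound the expected number of false positives, which may exceed 1).
#'
#' @slot geneIds character vector of gene identifiers.
#' @slot nStar observed N-statistic per gene.
#' @slot pValue permutation p-value per gene.
#' @slot pAdjusted extended-Bonferroni (PFER) adjusted p-value, p * m.
#' @slot K number of permutations used.
#' @slot G number of subgroups per condition.
#' @slot seed integer seed of the permutation plan.
#' @seealso [runGDAA()], [writeResultsTsv()]
#' @export
setClass("GdaaResult",
         representation(geneIds = "character", nStar = "numeric",
                        pValue = "numeric", pAdjusted = "numeric",
                        K = "integer", G = "integer", seed = "integer"))

setValidity("GdaaResult", function(object) {
    m <- length(object@geneIds)
    if (length(object@nStar) != m || length(object@pValue) != m ||
        length(object@pAdjusted) != m)
        return("per-gene vectors must all have length m")
    if (anyDuplicated(object@geneIds))
        return("gene ids must be unique")
    if (any(object@pValue < 0) || any(object@pValue > 1))
        return("p-values must lie in [0, 1]")
    grid <- object@pValue * object@K
    if (any(abs(grid - round(grid)) > 1e-9))
        return("every p-value must be an integer multiple of 1/K")
    if (!identical(object@pAdjusted, object@pValue * m))
        return("adjusted p-values must equal p * m exactly")
    if (any(object@nStar < -.N_STAT_NEG_TOL))
        return("observed N-statistics must be nonnegative up to roundoff")
    TRUE
})
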