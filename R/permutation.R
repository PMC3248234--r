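## Permutation machinery: a centrally generated, seeded plan of subject
## shuffles; per-permutation recomputation of subgroup correlation samples
## and N-statistics; permutation p-values; and the extended-Bonferroni
## (per-family error rate) adjustment.

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's state afterwards.  Generator is pinned (Mersenne-Twister,
## Rejection sampling) so plans are reproducible across R versions.
.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", envir = globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    expr
}

#' Generate a seeded permutation plan
#'
#' Draws K uniformly random permutations of the pooled 1..nTotal subject
#' indices from a single seeded Mersenne-Twister stream.  The plan is
#' generated once, centrally; workers consume index vectors from it and
#' never draw random numbers, which makes every downstream result a pure
#' function of (data, plan, G) regardless of the executor shape.
#'
#' @param nTotal pooled sample count (2n); must be even and >= 8.
#' @param K number of permutations (>= 1).
#' @param seed integer seed.
#' @return a [PermutationPlan-class].
#' @export
makePermutationPlan <- function(nTotal, K, seed) {
    nTotal <- as.integer(nTotal); K <- as.integer(K); seed <- as.integer(seed)
    if (nTotal %% 2L != 0L)
        stop("pooled sample count must be even (equal split of conditions)")
    if (nTotal < 8L)
        stop("pooled sample count must be at least 8 (n >= 4 per condition)")
    if (K < 1L) stop("K must be >= 1")
    perms <- .withSeed(seed, {
        t(vapply(seq_len(K), function(k) sample.int(nTotal),
                 integer(nTotal)))
    })
    new("PermutationPlan", seed = seed, K = K, nTotal = nTotal,
        perms = perms)
}

#' Split pooled samples into two permuted pseudo-conditions
#'
#' Columns `perm[1..n]` become pseudo-condition A', columns
#' `perm[n+1..2n]` pseudo-condition B', in permuted order.
#'
#' @param pooled numeric genes x 2n matrix.
#' @param perm integer permutation of 1..2n.
#' @return list with elements `A` and `B`, each genes x n.
#' @export
splitPermuted <- function(pooled, perm) {
    nTotal <- ncol(pooled)
    if (length(perm) != nTotal ||
        !identical(sort(as.integer(perm)), seq_len(nTotal)))
        stop("perm must be a permutation of 1..ncol(pooled)")
    n <- nTotal %/% 2L
    list(A = pooled[, perm[seq_len(n)], drop = FALSE],
         B = pooled[, perm[n + seq_len(n)], drop = FALSE])
}

#' N-statistics for one permutation of the pooled data
#'
#' Pure function of (pooled, perm, G): splits the shuffled subjects into
#' two equal pseudo-conditions, partitions each into G contiguous
#' subgroups (the shuffle provides the randomization), computes the moment
#' arrays and Fisher-transformed correlation samples per group, then the
#' per-gene N-statistics.  When `lanes > 1` the genes are processed in
#' [geneBlockSplit()] blocks, each block writing only its own range of the
#' output vector; the result is identical for any lane count.
#'
#' @param pooled numeric genes x 2n matrix.
#' @param perm integer permutation of 1..2n.
#' @param G number of subgroups per pseudo-condition.
#' @param lanes gene-block lanes (fine-grain split; default 1).
#' @return numeric vector of N-statistics, length `nrow(pooled)`.
#' @export
permutationStatistic <- function(pooled, perm, G, lanes = 1L) {
    halves <- splitPermuted(pooled, perm)
    n <- ncol(halves$A)
    part <- partitionSubgroups(n, G)
    momA <- computeSubgroupMoments(halves$A, part)
    momB <- computeSubgroupMoments(halves$B, part)
    corrA <- correlationSample(halves$A, part, momA)
    corrB <- correlationSample(halves$B, part, momB)
    m <- nrow(pooled)
    out <- numeric(m)
    for (block in geneBlockSplit(m, min(lanes, m)))
        out[block] <- nStatisticAll(corrA, corrB, rows = block)
    out
}

#' Permutation null distribution of the N-statistics
#'
#' Row k of the result is [permutationStatistic()] under the k-th
#' permutation of the plan, computed by the two-tier executor described in
#' [dispatch()].  The output is identical for every valid
#' [ExecutorConfig-class].
#'
#' @param pooled numeric genes x 2n matrix.
#' @param plan a [PermutationPlan-class].
#' @param G number of subgroups per pseudo-condition.
#' @param config an [ExecutorConfig-class] (default: sequential).
#' @return a [NullDistribution-class] (K x m).
#' @export
computeNull <- function(pooled, plan, G, config = executorConfig()) {
    handle <- publishSharedInputs(pooled)
    workFn <- function(k) {
        permutationStatistic(sharedExpression(handle), plan@perms[k, ], G,
                             lanes = config@lanes)
    }
    dispatch(plan, workFn, config)
}

#' Permutation p-values
#'
#' p_i = #(N_ik >= N_i*) / K: the proportion of permutation statistics at
#' least as large as the observed one, ties counting as exceedances.  No
#' +1 smoothing is applied, so p = 0 is possible; every p is an exact
#' multiple of 1/K.
#'
#' @param nStar numeric vector of observed N-statistics (length m).
#' @param null a [NullDistribution-class] with m columns.
#' @return numeric vector of p-values.
#' @export
permutationPValues <- function(nStar, null) {
    stats <- if (is(null, "NullDistribution")) null@stats else null
    if (length(nStar) != ncol(stats))
        stop("observed statistics and null distribution disagree on gene count")
    K <- nrow(stats)
    colSums(stats >= rep(nStar, each = K)) / K
}

#' Extended Bonferroni (PFER) adjustment
#'
#' p_tilde_i = p_i * m, deliberately not capped at 1: the adjusted value
#' bounds the per-family error rate (the expected number of false
#' positives across the m tests), which can exceed 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param m number of tests (defaults to `length(p)`).
#' @return adjusted p-values.
#' @export
adjustPValues <- function(p, m = length(p)) {
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    p * m
}

#' Gene differential association analysis
#'
#' The full procedure: (1) partition each condition's n subjects into G
#' contiguous subgroups, (2) compute each gene's Fisher-transformed
#' correlation vector in every subgroup, (3) compute the observed
#' N-statistic N_i* per gene from the 2 x G correlation-vector samples,
#' (4-7) pool all 2n subjects, reshuffle K times, and recompute the
#' statistics to build the permutation null, (8) permutation p-values,
#' (9) PFER-adjusted p-values p * m.  The result is fully determined by
#' (inputs, G, K, seed) and invariant to the executor configuration.
#'
#' @param exprA,exprB genes x samples matrices (or SummarizedExperiments;
#'   the first assay is used) for the two conditions; identical gene ids
#'   in identical order, equal sample counts.
#' @param G subgroups per condition, `1 <= G <= floor(n/2)`.
#' @param K number of permutations.
#' @param seed integer seed of the permutation plan.
#' @param config an [ExecutorConfig-class] (default: sequential).
#' @return a [GdaaResult-class].
#' @examples
#' sim <- generateDaPair(simulationConfig(m = 30, n = 20, daGenes = 5,
#'                                        rhoA = 0.9, rhoB = 0, seed = 7))
#' res <- runGDAA(sim$A, sim$B, G = 4, K = 50, seed = 7)
#' head(as.data.frame(res))
#' @export
runGDAA <- function(exprA, exprB, G, K, seed, config = executorConfig()) {
    exprA <- .asExpressionMatrix(exprA, "condition A")
    exprB <- .asExpressionMatrix(exprB, "condition B")
    validateExpression(exprA, what = "condition A")
    validateExpression(exprB, what = "condition B")
    if (!identical(rownames(exprA), rownames(exprB)))
        stop("the two conditions must share identical gene ids in identical order")
    n <- ncol(exprA)
    if (ncol(exprB) != n)
        stop("the two conditions must have equal sample counts")
    G <- as.integer(G); K <- as.integer(K); seed <- as.integer(seed)
    if (G < 1L || G > n %/% 2L)
        stop(sprintf("G must lie in [1, %d] for n = %d", n %/% 2L, n))
    validObject(config)

    ## Observed statistic (computed before any dispatch, master side).
    part <- partitionSubgroups(n, G)
    corrA <- correlationSample(exprA, part)
    corrB <- correlationSample(exprB, part)
    nStar <- nStatisticAll(corrA, corrB)

    ## Permutation null on the pooled, relabelled samples.
    pooled <- cbind(exprA, exprB)
    colnames(pooled) <- make.unique(c(paste0("A.", colnames(exprA)),
                                      paste0("B.", colnames(exprB))))
    plan <- makePermutationPlan(2L * n, K, seed)
    null <- computeNull(pooled, plan, G, config)

    p <- permutationPValues(nStar, null)
    new("GdaaResult", geneIds = rownames(exprA), nStar = nStar,
        pValue = p, pAdjusted = adjustPValues(p, nrow(exprA)),
        K = K, G = G, seed = seed)
}

#' Naive reference pipeline (oracle)
#'
#' End-to-end reimplementation through independent routes: correlations
#' via [stats::cor()] per gene pair within each subgroup, Fisher transform
#' via the clamped closed form, N-statistics via the literal
#' [nStatisticBruteForce()] loops with explicit entry-i exclusion, and
#' p-values by per-gene counting.  Shares only the permutation plan with
#' [runGDAA()] (the plan is an input, not a computation).  Quadratic per
#' gene - intended for small instances in equivalence tests.
#'
#' @inheritParams runGDAA
#' @return a [GdaaResult-class].
#' @export
runGDAAOracle <- function(exprA, exprB, G, K, seed) {
    exprA <- .asExpressionMatrix(exprA, "condition A")
    exprB <- .asExpressionMatrix(exprB, "condition B")
    validateExpression(exprA, what = "condition A")
    validateExpression(exprB, what = "condition B")
    if (!identical(rownames(exprA), rownames(exprB)))
        stop("the two conditions must share identical gene ids in identical order")
    n <- ncol(exprA)
    if (ncol(exprB) != n) stop("equal sample counts required")
    G <- as.integer(G); K <- as.integer(K); seed <- as.integer(seed)
    m <- nrow(exprA)

    naiveSample <- function(expr, part) {
        w <- lapply(part@subgroups, function(idx) {
            X <- expr[, idx, drop = FALSE]
            r <- suppressWarnings(stats::cor(t(X)))
            r[!is.finite(r)] <- 0
            r <- pmin(pmax(r, -.FISHER_CLAMP), .FISHER_CLAMP)
            wk <- 0.5 * log((1 + r) / (1 - r))
            diag(wk) <- 0
            wk[lower.tri(wk)] <- t(wk)[lower.tri(wk)]
            wk
        })
        new("CorrelationSample", w = w)
    }

    part <- partitionSubgroups(n, G)
    nStar <- nStatisticBruteForce(naiveSample(exprA, part),
                                  naiveSample(exprB, part))
    pooled <- cbind(exprA, exprB)
    colnames(pooled) <- make.unique(c(paste0("A.", colnames(exprA)),
                                      paste0("B.", colnames(exprB))))
    plan <- makePermutationPlan(2L * n, K, seed)
    null <- matrix(NA_real_, nrow = K, ncol = m)
    for (k in seq_len(K)) {
        halves <- splitPermuted(pooled, plan@perms[k, ])
        null[k, ] <- nStatisticBruteForce(naiveSample(halves$A, part),
                                          naiveSample(halves$B, part))
    }
    p <- vapply(seq_len(m), function(i) sum(null[, i] >= nStar[i]) / K,
                numeric(1))
    new("GdaaResult", geneIds = rownames(exprA), nStar = nStar,
        pValue = p, pAdjusted = adjustPValues(p, m),
        K = K, G = G, seed = seed)
}
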