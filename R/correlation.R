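## Subgroup partitioning and Fisher-transformed correlation-vector samples.
##
## Each condition's n subjects are split into G disjoint subgroups of >= 2
## subjects each (sizes differ by at most one).  Within each subgroup the
## full m x m Pearson correlation matrix is assembled from precomputed
## moment arrays (per-gene sums and sums of squares) plus one cross-product,
## Fisher-transformed, and the diagonal zeroed: row i is then gene i's
## correlation vector from that subgroup.

## Clamp before the Fisher transform: keeps w finite when |r| = 1 (e.g.
## duplicated genes within a subgroup).  The exact clamp value does not
## affect rankings; it only bounds the transform at ~14.2.
.FISHER_CLAMP <- 1 - 1e-12

#' Partition samples into contiguous, balanced subgroups
#'
#' Subgroup j receives a contiguous block of the current sample order;
#' sizes are as even as possible (they differ by at most one, the first
#' `n %% G` subgroups being larger) and every subgroup has at least two
#' subjects.  Under permutations the sample order is freshly shuffled, so
#' contiguous assignment there is equivalent to a random partition.
#'
#' @param n sample count.
#' @param G number of subgroups, `1 <= G <= floor(n/2)`.
#' @return a [SubgroupPartition-class].
#' @examples
#' partitionSubgroups(7, 3)  # sizes 3, 2, 2
#' @export
partitionSubgroups <- function(n, G) {
    n <- as.integer(n); G <- as.integer(G)
    if (G < 1L)
        stop("G must be >= 1")
    if (G > n %/% 2L)
        stop(sprintf(
            "G = %d is too large for n = %d: every subgroup needs at least two subjects (G <= %d)",
            G, n, n %/% 2L))
    base <- n %/% G
    extra <- n %% G
    sizes <- rep(base, G) + c(rep(1L, extra), rep(0L, G - extra))
    ends <- cumsum(sizes)
    starts <- ends - sizes + 1L
    sg <- lapply(seq_len(G), function(j) seq.int(starts[j], ends[j]))
    new("SubgroupPartition", subgroups = lapply(sg, as.integer))
}

#' Number of subgroups in a partition
#' @param part a [SubgroupPartition-class].
#' @return integer count G.
#' @export
nSubgroups <- function(part) length(part@subgroups)

#' Subgroup sizes of a partition
#' @param part a [SubgroupPartition-class].
#' @return integer vector of sizes.
#' @export
subgroupSizes <- function(part) lengths(part@subgroups)

#' Per-gene, per-subgroup sums and sums of squares
#'
#' Computes the two m x G moment arrays used by the correlation step: the
#' within-subgroup sums and sums of squares of each gene's expression.
#' They are computed once per (permutation, condition) and read-shared by
#' all gene-block lanes.
#'
#' @param expr numeric genes x samples matrix.
#' @param part a [SubgroupPartition-class] over `ncol(expr)`.
#' @return a [SubgroupMoments-class].
#' @export
computeSubgroupMoments <- function(expr, part) {
    sg <- part@subgroups
    if (max(unlist(sg)) > ncol(expr))
        stop("partition indices exceed the number of samples")
    G <- length(sg)
    sums <- matrix(0, nrow = nrow(expr), ncol = G)
    sumsSq <- matrix(0, nrow = nrow(expr), ncol = G)
    for (j in seq_len(G)) {
        xj <- expr[, sg[[j]], drop = FALSE]
        sums[, j] <- rowSums(xj)
        sumsSq[, j] <- rowSums(xj * xj)
    }
    new("SubgroupMoments", sums = sums, sumsSq = sumsSq,
        sizes = lengths(sg))
}

#' Pearson correlation from the raw-moment formula
#'
#' Evaluates r = (n Sxy - Sx Sy) / (sqrt(n Sxx - Sx^2) sqrt(n Syy - Sy^2)),
#' the cross-product form used throughout the pipeline.  If either vector
#' has (numerically) zero variance the correlation is undefined; by
#' convention 0 is returned with a warning, so a degenerate gene cannot
#' abort a long permutation run.  `strict = TRUE` turns that into an error.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @param strict error instead of warning on zero variance.
#' @return correlation in [-1, 1] (up to roundoff).
#' @examples
#' pearsonCorrelation(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearsonCorrelation <- function(x, y, strict = FALSE) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    n <- length(x)
    if (n < 2L)
        stop("correlation needs at least two observations")
    num <- n * sum(x * y) - sum(x) * sum(y)
    dx <- n * sum(x * x) - sum(x)^2
    dy <- n * sum(y * y) - sum(y)^2
    tol <- .Machine$double.eps * n * 100
    if (dx <= tol * max(sum(x * x), 1) || dy <= tol * max(sum(y * y), 1)) {
        msg <- "zero-variance vector in Pearson correlation; returning 0"
        if (strict) stop(msg)
        warning(msg)
        return(0)
    }
    num / (sqrt(dx) * sqrt(dy))
}

#' Fisher z-transformation
#'
#' w = atanh(r) = (1/2) log((1 + r) / (1 - r)), with r first clamped to
#' |r| <= 1 - 1e-12 so the result is always finite (perfectly correlated
#' genes map to ~14.2 rather than Inf, which would poison the Euclidean
#' kernels downstream).
#'
#' @param r numeric vector of correlations in [-1, 1] (values beyond 1 by
#'   more than 1e-8 are rejected as usage errors).
#' @return transformed values, finite.
#' @export
fisherTransform <- function(r) {
    if (any(abs(r) > 1 + 1e-8))
        stop("correlations must lie in [-1, 1]")
    r <- pmin(pmax(r, -.FISHER_CLAMP), .FISHER_CLAMP)
    atanh(r)
}

#' Fisher-transformed correlation matrices for all subgroups
#'
#' For each subgroup k, assembles the m x m Pearson correlation matrix from
#' the moment arrays plus the within-subgroup cross-product, applies the
#' Fisher transform (with clamping), zeroes the diagonal, and enforces exact
#' symmetry.  Genes with zero variance inside a subgroup get correlation 0
#' against everything (with a warning; see [pearsonCorrelation()]).
#'
#' @param expr numeric genes x samples matrix.
#' @param part a [SubgroupPartition-class].
#' @param moments optional precomputed [SubgroupMoments-class]; computed
#'   on the fly when missing.
#' @param strict error instead of warning on zero-variance genes.
#' @return a [CorrelationSample-class].
#' @export
correlationSample <- function(expr, part, moments = NULL, strict = FALSE) {
    if (is.null(moments))
        moments <- computeSubgroupMoments(expr, part)
    sg <- part@subgroups
    G <- length(sg)
    m <- nrow(expr)
    w <- vector("list", G)
    for (k in seq_len(G)) {
        idx <- sg[[k]]
        s <- length(idx)
        X <- expr[, idx, drop = FALSE]
        cp <- tcrossprod(X)                      # m x m cross-products
        sk <- moments@sums[, k]
        d <- s * moments@sumsSq[, k] - sk^2      # s * (s-1) * var-ish scale
        tol <- .Machine$double.eps * s * 100
        zv <- d <= tol * pmax(moments@sumsSq[, k], 1)
        if (any(zv)) {
            msg <- sprintf(
                "%d gene(s) with zero variance in subgroup %d; correlations set to 0",
                sum(zv), k)
            if (strict) stop(msg)
            warning(msg)
        }
        num <- s * cp - outer(sk, sk)
        dc <- d
        dc[zv] <- 1                              # avoid 0/0; rows zeroed below
        r <- num / (sqrt(dc) %o% sqrt(dc))
        if (any(zv)) { r[zv, ] <- 0; r[, zv] <- 0 }
        r <- pmin(pmax(r, -.FISHER_CLAMP), .FISHER_CLAMP)
        wk <- atanh(r)
        diag(wk) <- 0
        wk[lower.tri(wk)] <- t(wk)[lower.tri(wk)]  # exact symmetry
        w[[k]] <- wk
    }
    ans <- new("CorrelationSample", w = w)
    stopifnot(m == nrow(w[[1L]]))
    ans
}
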