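## The energy-distance N-statistic with the Euclidean kernel, per gene:
##
##   N_i = 2/G^2 sum_{k,l} L(w_i(A,k), w_i(B,l))
##       - 1/G^2 sum_{k,l} L(w_i(A,k), w_i(A,l))
##       - 1/G^2 sum_{k,l} L(w_i(B,k), w_i(B,l))
##
## where L is the Euclidean distance between gene i's correlation vectors
## (entry i excluded).  The within-group sums run over all G^2 ordered
## pairs exactly as written (k = l self-pairs contribute 0); accumulation
## is k-major then l, so results are bit-identical across parallel
## configurations.  Nonnegative up to roundoff for any inputs.

#' Euclidean distance kernel
#'
#' @param a,b numeric vectors of equal length.
#' @return the Euclidean distance ||a - b||.
#' @export
euclideanKernel <- function(a, b) {
    if (length(a) != length(b))
        stop("kernel arguments must have equal length")
    sqrt(sum((a - b)^2))
}

#' N-statistic for one gene from two samples of correlation vectors
#'
#' Literal evaluation over the `2 x G` correlation vectors of a single
#' gene: the between-condition kernel sum (weight 2/G^2) minus each
#' within-condition sum (weight 1/G^2), each over all G^2 ordered pairs.
#'
#' @param samplesA,samplesB lists of G equal-length numeric vectors (gene
#'   i's correlation vector from each subgroup of each condition).
#' @return the N-statistic (scalar, nonnegative up to roundoff).
#' @export
nStatisticGene <- function(samplesA, samplesB) {
    G <- length(samplesA)
    if (length(samplesB) != G)
        stop("both conditions must contribute G correlation vectors")
    len <- unique(c(lengths(samplesA), lengths(samplesB)))
    if (length(len) != 1L)
        stop("all correlation vectors must have equal length")
    sAB <- 0; sAA <- 0; sBB <- 0
    for (k in seq_len(G)) for (l in seq_len(G))
        sAB <- sAB + euclideanKernel(samplesA[[k]], samplesB[[l]])
    for (k in seq_len(G)) for (l in seq_len(G))
        sAA <- sAA + euclideanKernel(samplesA[[k]], samplesA[[l]])
    for (k in seq_len(G)) for (l in seq_len(G))
        sBB <- sBB + euclideanKernel(samplesB[[k]], samplesB[[l]])
    (2 * sAB - sAA - sBB) / G^2
}

## Vectorized core: per-gene N-statistics for a subset of gene rows.
## Because the diagonal of every correlation matrix is 0, full-row
## distances equal distances between the entry-i-excluded vectors, and one
## rowSums per ordered pair handles every gene in the block at once.
##
## Accumulation order is fixed and deterministic (so parallel
## configurations are bit-identical) and grouped by unordered subgroup
## pair: every sum adds its (k, k) diagonal terms first, then
## d(k, l) + d(l, k) for k < l, the two distances of a pair added together
## before accumulation.  All G^2 ordered-pair terms are included (no
## normalization shortcut), and by commutativity of IEEE addition this
## grouping makes the statistic exactly symmetric in its arguments and
## exactly zero when the two samples are equal.
.nStatisticRows <- function(wA, wB, rows) {
    G <- length(wA)
    dist2 <- function(M1, M2) {
        D <- M1[rows, , drop = FALSE] - M2[rows, , drop = FALSE]
        unname(sqrt(rowSums(D * D)))
    }
    pairSum <- function(w1, w2) {
        acc <- numeric(length(rows))
        for (k in seq_len(G)) acc <- acc + dist2(w1[[k]], w2[[k]])
        if (G > 1L)
            for (k in seq_len(G - 1L)) for (l in seq.int(k + 1L, G))
                acc <- acc + (dist2(w1[[k]], w2[[l]]) + dist2(w1[[l]], w2[[k]]))
        acc
    }
    (2 * pairSum(wA, wB) - (pairSum(wA, wA) + pairSum(wB, wB))) / G^2
}

#' N-statistics for all genes (vectorized)
#'
#' Entry i of the result equals [nStatisticGene()] applied to the i-th
#' rows of the two conditions' subgroup correlation matrices.  The
#' computation is batched over genes via full-row Euclidean distances
#' (valid because the diagonals are zero) and accumulated in a fixed
#' order, so it agrees with the per-gene path to machine precision and is
#' invariant to how genes are split across lanes.
#'
#' @param corrA,corrB [CorrelationSample-class] objects with identical
#'   G and m.
#' @param rows optional integer vector of gene rows to compute (defaults
#'   to all genes).
#' @return numeric vector of N-statistics (length `length(rows)`).
#' @export
nStatisticAll <- function(corrA, corrB, rows = NULL) {
    if (length(corrA@w) != length(corrB@w))
        stop("both conditions must have the same number of subgroups")
    m <- nrow(corrA@w[[1L]])
    if (nrow(corrB@w[[1L]]) != m)
        stop("both conditions must cover the same genes")
    if (is.null(rows)) rows <- seq_len(m)
    .nStatisticRows(corrA@w, corrB@w, rows)
}

#' Brute-force reference N-statistics
#'
#' A literal transcription used as an independent oracle for
#' [nStatisticAll()]: loops over genes, ordered subgroup pairs and vector
#' coordinates, excluding entry i explicitly rather than relying on the
#' zero-diagonal convention.  Quadratic per gene; intended for m <= ~30.
#'
#' @inheritParams nStatisticAll
#' @return numeric vector of N-statistics, length m.
#' @export
nStatisticBruteForce <- function(corrA, corrB) {
    G <- length(corrA@w)
    if (length(corrB@w) != G)
        stop("both conditions must have the same number of subgroups")
    m <- nrow(corrA@w[[1L]])
    vapply(seq_len(m), function(i) {
        a <- lapply(seq_len(G), function(k) corrA@w[[k]][i, -i])
        b <- lapply(seq_len(G), function(k) corrB@w[[k]][i, -i])
        nStatisticGene(a, b)
    }, numeric(1))
}
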