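# Fixtures are generated in code; nothing is read from disk.

# Random genes x samples matrix with valid dimnames.
randExpr <- function(m, n, seed = 1, prefix = "s") {
    set.seed(seed)
    matrix(rnorm(m * n), nrow = m,
           dimnames = list(sprintf("g%02d", seq_len(m)),
                           sprintf("%s%02d", prefix, seq_len(n))))
}

# Naive per-pair correlation sample: loops over gene pairs calling the
# scalar pearsonCorrelation + fisherTransform operations.  Independent of
# the vectorized moments-based path it is used to check.
naiveCorrelationSample <- function(expr, part) {
    m <- nrow(expr)
    w <- lapply(part@subgroups, function(idx) {
        wk <- matrix(0, m, m)
        for (i in seq_len(m)) for (j in seq_len(m)) {
            if (i == j) next
            wk[i, j] <- fisherTransform(suppressWarnings(
                pearsonCorrelation(expr[i, idx], expr[j, idx])))
        }
        wk[lower.tri(wk)] <- t(wk)[lower.tri(wk)]
        wk
    })
    new("CorrelationSample", w = w)
}

# Random CorrelationSample pair with shared (m, G) for statistic tests.
randCorrPair <- function(m, G, n = 16, seed = 1) {
    part <- partitionSubgroups(n, G)
    A <- correlationSample(randExpr(m, n, seed = seed), part)
    B <- correlationSample(randExpr(m, n, seed = seed + 10000), part)
    list(A = A, B = B)
}

# Minimal valid GdaaResult for IO tests.
makeResult <- function(p, K, nStar = rep(1, length(p)), G = 2L, seed = 1L) {
    m <- length(p)
    new("GdaaResult", geneIds = sprintf("g%02d", seq_len(m)),
        nStar = as.numeric(nStar), pValue = as.numeric(p),
        pAdjusted = as.numeric(p) * m, K = as.integer(K),
        G = as.integer(G), seed = as.integer(seed))
}
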