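test_that("permutation plans are seeded, deterministic bijections", {
    p1 <- makePermutationPlan(8, 3, seed = 1)
    p2 <- makePermutationPlan(8, 3, seed = 1)
    expect_identical(p1@perms, p2@perms)
    expect_false(identical(p1@perms, makePermutationPlan(8, 3, seed = 2)@perms))
    for (k in 1:3)
        expect_identical(sort(p1@perms[k, ]), 1:8)

    expect_error(makePermutationPlan(7, 3, 1), "even")
    expect_error(makePermutationPlan(6, 3, 1), "at least 8")
    expect_error(makePermutationPlan(8, 0, 1), "K must be")

    # first-position value approximately uniform over 1..8
    plan <- makePermutationPlan(8, 1000, seed = 2)
    tab <- tabulate(plan@perms[, 1], nbins = 8)
    expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("splitting a permuted pool partitions the samples", {
    pooled <- randExpr(4, 12, seed = 6)
    n <- 6L
    halves <- splitPermuted(pooled, 1:12)
    expect_identical(halves$A, pooled[, 1:6])
    expect_identical(halves$B, pooled[, 7:12])

    swapped <- splitPermuted(pooled, c(7:12, 1:6))
    expect_identical(swapped$A, pooled[, 7:12])
    expect_identical(swapped$B, pooled[, 1:6])

    set.seed(8)
    for (rep in 1:5) {
        perm <- sample(12)
        halves <- splitPermuted(pooled, perm)
        ids <- c(colnames(halves$A), colnames(halves$B))
        expect_setequal(ids, colnames(pooled))
        expect_identical(anyDuplicated(ids), 0L)
    }
    expect_error(splitPermuted(pooled, c(1:11, 11)), "permutation")
})

test_that("per-permutation statistics are pure and lane-invariant", {
    A <- randExpr(6, 6, seed = 10, prefix = "a")
    pooled <- cbind(A, A)
    colnames(pooled) <- paste0("s", 1:12)

    # identity permutation on a duplicated pool: both pseudo-conditions
    # identical, so the statistic vector is exactly zero
    expect_identical(permutationStatistic(pooled, 1:12, G = 3), rep(0, 6))

    pooled2 <- cbind(randExpr(6, 6, seed = 11, prefix = "a"),
                     randExpr(6, 6, seed = 12, prefix = "b"))
    perm <- makePermutationPlan(12, 1, seed = 3)@perms[1, ]
    s1 <- permutationStatistic(pooled2, perm, G = 3)
    expect_identical(permutationStatistic(pooled2, perm, G = 3), s1)  # purity
    for (lanes in c(2L, 3L, 6L, 11L))  # lane count never changes values
        expect_identical(permutationStatistic(pooled2, perm, G = 3,
                                              lanes = lanes), s1)

    # end-to-end against the naive route: cor() + brute-force loops
    halves <- splitPermuted(pooled2, perm)
    part <- partitionSubgroups(6, 3)
    naive <- nStatisticBruteForce(naiveCorrelationSample(halves$A, part),
                                  naiveCorrelationSample(halves$B, part))
    expect_lt(max(abs(s1 - naive)), 1e-10)
})

test_that("computeNull stacks per-permutation statistics by plan index", {
    pooled <- cbind(randExpr(5, 4, seed = 13, prefix = "a"),
                    randExpr(5, 4, seed = 14, prefix = "b"))
    plan <- makePermutationPlan(8, 4, seed = 5)
    null <- computeNull(pooled, plan, G = 2)
    expect_identical(dim(nullStats(null)), c(4L, 5L))
    for (k in 1:4)
        expect_identical(nullStats(null)[k, ],
                         permutationStatistic(pooled, plan@perms[k, ], G = 2))
})

test_that("p-values count ties as exceedances on the 1/K grid", {
    nullOf <- function(x) new("NullDistribution",
                              stats = matrix(x, ncol = 1))
    expect_identical(permutationPValues(5, nullOf(c(1, 2, 3, 4))), 0)
    expect_identical(permutationPValues(2.5, nullOf(c(1, 2, 3, 4))), 0.5)
    expect_identical(permutationPValues(3, nullOf(c(3, 3, 1, 1))), 0.5)
    expect_error(permutationPValues(c(1, 2), nullOf(1:4)), "gene count")

    # monotone non-increasing in the observed statistic; always on the grid
    null <- nullOf(runif(20))
    ns <- sort(runif(15))
    ps <- vapply(ns, permutationPValues, numeric(1), null = null)
    expect_true(all(diff(ps) <= 0))
    expect_identical(ps, round(ps * 20) / 20)   # exactly count/K
})

test_that("the PFER adjustment multiplies by m without capping", {
    expect_equal(adjustPValues(0.001, m = 7084), 7.084)
    expect_identical(adjustPValues(0, m = 100), 0)
    expect_identical(adjustPValues(c(0.5), m = 10), 5)
    expect_error(adjustPValues(1.2), "\\[0, 1\\]")
})

test_that("runGDAA on a duplicated condition yields the degenerate null result", {
    A <- randExpr(8, 8, seed = 20)
    B <- A
    colnames(B) <- paste0("b", 1:8)
    # permuted size-2 subgroups can pair a column with its duplicate,
    # triggering the zero-variance convention; that is expected here
    res <- suppressWarnings(runGDAA(A, B, G = 3, K = 25, seed = 4))
    expect_true(all(abs(nStar(res)) <= 1e-12))
    expect_identical(pValues(res), rep(1, 8))
    expect_identical(pAdjusted(res), rep(8, 8))
})

test_that("runGDAA rejects inconsistent inputs before computing", {
    A <- randExpr(6, 8, seed = 21, prefix = "a")
    B <- randExpr(6, 8, seed = 22, prefix = "b")
    Bbad <- B; rownames(Bbad) <- rev(rownames(B))
    expect_error(runGDAA(A, Bbad, G = 2, K = 5, seed = 1), "gene ids")
    expect_error(runGDAA(A, B[, 1:6], G = 2, K = 5, seed = 1),
                 "equal sample counts")
    expect_error(runGDAA(A, B, G = 5, K = 5, seed = 1), "G must lie")
    expect_error(runGDAA(A[1, , drop = FALSE], B[1, , drop = FALSE],
                         G = 2, K = 5, seed = 1), "at least 2 genes")
})

test_that("the full pipeline matches the naive oracle pipeline", {
    A <- randExpr(6, 6, seed = 23, prefix = "a")
    B <- randExpr(6, 6, seed = 24, prefix = "b")
    fast <- runGDAA(A, B, G = 3, K = 20, seed = 9)
    slow <- runGDAAOracle(A, B, G = 3, K = 20, seed = 9)
    expect_lt(max(abs(nStar(fast) - nStar(slow))), 1e-10)
    expect_identical(pValues(fast), pValues(slow))
    expect_identical(pAdjusted(fast), pAdjusted(slow))
})

test_that("results are reproducible and SummarizedExperiment input is accepted", {
    A <- randExpr(5, 8, seed = 25, prefix = "a")
    B <- randExpr(5, 8, seed = 26, prefix = "b")
    r1 <- runGDAA(A, B, G = 2, K = 10, seed = 11)
    r2 <- runGDAA(A, B, G = 2, K = 10, seed = 11)
    expect_identical(as.data.frame(r1), as.data.frame(r2))

    skip_if_not_installed("SummarizedExperiment")
    seA <- SummarizedExperiment::SummarizedExperiment(assays = list(logexpr = A))
    r3 <- runGDAA(seA, B, G = 2, K = 10, seed = 11)
    expect_identical(as.data.frame(r3), as.data.frame(r1))
})
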