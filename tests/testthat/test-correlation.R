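test_that("subgroup partitions are contiguous, balanced, and sized >= 2", {
    # n = 100, G = 10: ten subgroups of ten
    p <- partitionSubgroups(100, 10)
    expect_identical(unname(subgroupSizes(p)), rep(10L, 10))
    expect_identical(p@subgroups[[1]], 1:10)
    expect_identical(p@subgroups[[10]], 91:100)

    # n = 7, G = 3: sizes (3, 2, 2)
    expect_identical(unname(subgroupSizes(partitionSubgroups(7, 3))),
                     c(3L, 2L, 2L))

    # a subgroup of one subject is never allowed
    expect_error(partitionSubgroups(5, 3), "two subjects")
    expect_error(partitionSubgroups(10, 0), ">= 1")

    # property: sizes within 1 of each other, all >= 2, union = 1..n
    for (n in 4:30) for (G in seq_len(n %/% 2)) {
        p <- partitionSubgroups(n, G)
        sz <- subgroupSizes(p)
        expect_true(all(sz >= 2L))
        expect_lte(max(sz) - min(sz), 1L)
        expect_identical(sort(unlist(p@subgroups)), seq_len(n))
    }
})

test_that("subgroup moments equal exact per-element sums", {
    x <- matrix(c(1, 2, 3, 4), nrow = 1,
                dimnames = list("g1", paste0("s", 1:4)))
    x <- rbind(x, g2 = 0)
    mom <- computeSubgroupMoments(x, partitionSubgroups(4, 2))
    expect_identical(unname(mom@sums[1, ]), c(3, 7))
    expect_identical(unname(mom@sumsSq[1, ]), c(5, 25))
    expect_identical(unname(mom@sums[2, ]), c(0, 0))
    expect_identical(unname(mom@sumsSq[2, ]), c(0, 0))

    # random matrix vs a naive double loop
    x <- randExpr(10, 8, seed = 2)
    part <- partitionSubgroups(8, 2)
    mom <- computeSubgroupMoments(x, part)
    for (i in 1:10) for (j in 1:2) {
        idx <- part@subgroups[[j]]
        s <- 0; ss <- 0
        for (l in idx) { s <- s + x[i, l]; ss <- ss + x[i, l]^2 }
        expect_equal(mom@sums[i, j], s)
        expect_equal(mom@sumsSq[i, j], ss)
    }
})

test_that("Pearson correlation follows the raw-moment formula and its conventions", {
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(2, 4, 6)), 1)
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(6, 4, 2)), -1)
    # (3*13 - 6*6) / (sqrt(6) * sqrt(6)) = 0.5
    expect_equal(pearsonCorrelation(c(1, 2, 3), c(1, 3, 2)), 0.5)

    expect_warning(r0 <- pearsonCorrelation(c(1, 2, 3), c(5, 5, 5)),
                   "zero-variance")
    expect_identical(r0, 0)
    expect_error(pearsonCorrelation(c(1, 2, 3), c(5, 5, 5), strict = TRUE),
                 "zero-variance")
    expect_error(pearsonCorrelation(1:3, 1:4), "equal length")
    expect_error(pearsonCorrelation(1, 2), "at least two")

    # affine invariance: positive slope preserves r, negative slope flips it
    set.seed(9)
    for (rep in 1:10) {
        x <- rnorm(7); y <- rnorm(7)
        r <- pearsonCorrelation(x, y)
        expect_equal(pearsonCorrelation(2.5 * x + 3, y), r, tolerance = 1e-12)
        expect_equal(pearsonCorrelation(x, -0.7 * y + 1), -r,
                     tolerance = 1e-12)
    }
})

test_that("Fisher transform is the clamped inverse hyperbolic tangent", {
    expect_identical(fisherTransform(0), 0)
    expect_equal(fisherTransform(tanh(1)), 1)
    # clamped at |r| = 1 - 1e-12, so perfectly correlated pairs stay finite
    w1 <- fisherTransform(1)
    expect_true(is.finite(w1))
    rc <- 1 - 1e-12
    expect_equal(w1, 0.5 * log((1 + rc) / (1 - rc)))  # ~14.16
    expect_equal(w1, 14.162, tolerance = 1e-4)
    expect_equal(fisherTransform(-1), -w1)
    expect_error(fisherTransform(1.01), "\\[-1, 1\\]")

    # odd and monotone on a grid
    r <- seq(-0.99, 0.99, by = 0.03)
    expect_equal(fisherTransform(-r), -fisherTransform(r))
    expect_true(all(diff(fisherTransform(r)) > 0))
})

test_that("moments-based correlation sample matches the naive per-pair oracle", {
    for (case in list(c(m = 6, n = 8, G = 2, seed = 1),
                      c(m = 12, n = 10, G = 3, seed = 2),
                      c(m = 25, n = 16, G = 4, seed = 3))) {
        x <- randExpr(case["m"], case["n"], seed = case["seed"])
        part <- partitionSubgroups(case["n"], case["G"])
        fast <- correlationSample(x, part)
        slow <- naiveCorrelationSample(x, part)
        for (k in seq_len(nSubgroups(part)))
            expect_lt(max(abs(fast@w[[k]] - slow@w[[k]])), 1e-10)
    }
})

test_that("moments-based correlation agrees with the two-pass (mean-centred) estimate", {
    x <- randExpr(15, 12, seed = 4)
    part <- partitionSubgroups(12, 3)
    fast <- correlationSample(x, part)
    for (k in 1:3) {
        r2 <- cor(t(x[, part@subgroups[[k]]]))
        w2 <- atanh(pmin(pmax(r2, -(1 - 1e-12)), 1 - 1e-12))
        diag(w2) <- 0
        expect_equal(fast@w[[k]], w2, tolerance = 1e-9,
                     ignore_attr = TRUE)
    }
})

test_that("correlation sample enforces its structural conventions", {
    x <- randExpr(8, 8, seed = 5)
    x[2, ] <- x[1, ]   # duplicated gene: r = 1 within every subgroup
    part <- partitionSubgroups(8, 2)
    cs <- correlationSample(x, part)
    for (k in 1:2) {
        wk <- cs@w[[k]]
        expect_identical(wk, t(wk))             # exact symmetry
        expect_identical(unname(diag(wk)), rep(0, 8))
        expect_true(all(is.finite(wk)))
        expect_equal(wk[1, 2], fisherTransform(1))
    }

    # zero-variance gene: warns (once per affected subgroup), errors in strict mode
    x[3, ] <- 7
    expect_warning(
        expect_warning(cs <- correlationSample(x, part), "zero variance"),
        "zero variance")
    expect_true(all(cs@w[[1]][3, ] == 0))
    expect_error(correlationSample(x, part, strict = TRUE), "zero variance")
})
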