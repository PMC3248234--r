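## Seeded generators for two-condition expression matrices with known
## differential-association structure.  The planted block follows the
## Gaussian factor construction x = sqrt(rho) f + sqrt(1 - rho) sigma e
## (one latent factor per sample), which yields an equicorrelated block
## with within-block correlation exactly rho when sigma = 1.  Baseline
## genes are independent standard normals, so the only signal separating
## the conditions is the change in the block's correlation, the quantity
## this test targets.

.geneIds <- function(m) sprintf("g%0*d", nchar(m), seq_len(m))
.sampleIds <- function(prefix, n) sprintf("%s_s%0*d", prefix, nchar(n),
                                          seq_len(n))

#' Construct a simulation configuration
#'
#' Defaults describe the standard planted-block recovery setting used in
#' the package's checks: 200 genes, 60 samples per condition, a 20-gene
#' block equicorrelated at 0.8 in condition A and uncorrelated in B.
#'
#' @param m gene count.
#' @param n samples per condition.
#' @param daGenes number of planted differentially associated genes.
#' @param rhoA,rhoB within-block correlation under each condition, in
#'   [0, 1).
#' @param noiseSd residual standard deviation (1 gives within-block
#'   correlation exactly rho).
#' @param seed integer seed.
#' @return a [SimulationConfig-class].
#' @export
simulationConfig <- function(m = 200L, n = 60L, daGenes = 20L,
                             rhoA = 0.8, rhoB = 0, noiseSd = 1,
                             seed = 1L) {
    new("SimulationConfig", m = as.integer(m), n = as.integer(n),
        daGenes = as.integer(daGenes), rhoA = as.numeric(rhoA),
        rhoB = as.numeric(rhoB), noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}

#' Generate a global-null pair of expression matrices
#'
#' Both conditions are drawn i.i.d. from the same distribution
#' (independent standard normal per gene and sample), so no gene is
#' differentially associated; used for type-I-error checks.
#'
#' @param m gene count (>= 2).
#' @param n samples per condition (>= 4).
#' @param seed integer seed.
#' @return list with genes x samples matrices `A` and `B`.
#' @export
generateNullPair <- function(m, n, seed) {
    m <- as.integer(m); n <- as.integer(n)
    if (m < 2L || n < 4L)
        stop("need m >= 2 genes and n >= 4 samples per condition")
    .withSeed(seed, {
        A <- matrix(stats::rnorm(m * n), nrow = m,
                    dimnames = list(.geneIds(m), .sampleIds("A", n)))
        B <- matrix(stats::rnorm(m * n), nrow = m,
                    dimnames = list(.geneIds(m), .sampleIds("B", n)))
        list(A = A, B = B)
    })
}

## One condition: block genes from the factor construction, the rest
## independent N(0, 1).
.simCondition <- function(m, n, block, rho, noiseSd) {
    x <- matrix(stats::rnorm(m * n), nrow = m)
    if (length(block) && rho > 0) {
        f <- stats::rnorm(n)                    # shared factor per sample
        eps <- x[block, , drop = FALSE]
        x[block, ] <- sqrt(rho) * rep(f, each = length(block)) +
            sqrt(1 - rho) * noiseSd * eps
    }
    x
}

#' Generate a pair of matrices with a planted differential-association block
#'
#' The first `daGenes` genes form an equicorrelated block with correlation
#' `rhoA` in condition A and `rhoB` in condition B; all other genes are
#' independent in both conditions.  When `rhoA == rhoB` the pair is
#' distributionally a global null.  Marginal means and variances of the
#' block genes are unchanged (for `noiseSd = 1`), so the planted signal
#' lives purely in the correlation structure.
#'
#' @param config a [SimulationConfig-class].
#' @return list with matrices `A`, `B` and `truth`, the integer indices of
#'   the planted genes.
#' @export
generateDaPair <- function(config = simulationConfig()) {
    validObject(config)
    m <- config@m; n <- config@n
    block <- seq_len(config@daGenes)
    .withSeed(config@seed, {
        A <- .simCondition(m, n, block, config@rhoA, config@noiseSd)
        B <- .simCondition(m, n, block, config@rhoB, config@noiseSd)
        dimnames(A) <- list(.geneIds(m), .sampleIds("A", n))
        dimnames(B) <- list(.geneIds(m), .sampleIds("B", n))
        list(A = A, B = B, truth = as.integer(block))
    })
}
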