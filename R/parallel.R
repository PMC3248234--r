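## Two-tier deterministic executor.
##
## Coarse grain: worker processes pull permutations one at a time from the
## plan (dynamic, single-permutation granularity).  Fine grain: inside a
## worker the genes are split into contiguous blocks ("lanes") that share
## one logical copy of the permuted data and moment arrays and each write
## only their own range of the per-permutation statistic vector.  Results
## are keyed by permutation index, never by arrival order, so out-of-order
## completion cannot perturb the null matrix and every configuration yields
## byte-identical output.

#' Construct an executor configuration
#'
#' @param nWorkers permutation-level worker processes (coarse grain).
#' @param lanes gene-block lanes per worker (fine grain).
#' @param maxInFlight optional cap on simultaneously dispatched
#'   permutations; `NA` means no cap beyond `nWorkers`.
#' @return an [ExecutorConfig-class].
#' @examples
#' executorConfig(nWorkers = 2, lanes = 2)
#' @export
executorConfig <- function(nWorkers = 1L, lanes = 1L, maxInFlight = NA) {
    new("ExecutorConfig", nWorkers = as.integer(nWorkers),
        lanes = as.integer(lanes), maxInFlight = as.integer(maxInFlight))
}

#' Split genes into contiguous, balanced blocks
#'
#' Block sizes differ by at most one (the first `m %% P` blocks are
#' larger); together the blocks cover 1..m disjointly.  Used by the
#' fine-grain tier to assign each lane its gene range.
#'
#' @param m gene count.
#' @param P number of lanes, `1 <= P <= m`.
#' @return list of P integer index ranges.
#' @examples
#' lengths(geneBlockSplit(7084, 3))  # 2362 2361 2361
#' @export
geneBlockSplit <- function(m, P) {
    m <- as.integer(m); P <- as.integer(P)
    if (P < 1L) stop("P must be >= 1")
    if (P > m) stop(sprintf("cannot split %d genes across %d lanes", m, P))
    base <- m %/% P
    extra <- m %% P
    sizes <- rep(base, P) + c(rep(1L, extra), rep(0L, P - extra))
    ends <- cumsum(sizes)
    lapply(seq_len(P), function(j) seq.int(ends[j] - sizes[j] + 1L, ends[j]))
}

#' Publish read-shared inputs for workers
#'
#' Wraps the pooled expression matrix in a locked environment: workers and
#' lanes read it through [sharedExpression()] but cannot rebind it, making
#' the read-only contract explicit (and assertable by checksumming before
#' and after a run).  Under the fork-based worker backend all workers see
#' this single logical copy via copy-on-write.
#'
#' @param pooled numeric genes x samples matrix.
#' @return an opaque handle.
#' @export
publishSharedInputs <- function(pooled) {
    e <- new.env(parent = emptyenv())
    e$expr <- pooled
    lockEnvironment(e, bindings = TRUE)
    class(e) <- "GdaaSharedInputs"
    e
}

#' Read the expression matrix from a shared-inputs handle
#' @param handle handle from [publishSharedInputs()].
#' @return the published matrix.
#' @export
sharedExpression <- function(handle) {
    stopifnot(inherits(handle, "GdaaSharedInputs"))
    handle[["expr"]]
}

## One batch of permutation indices through the worker pool.  Fork-based
## workers (mclapply, mc.preschedule = FALSE) give pull-based dynamic
## assignment at single-permutation granularity; without fork support (or
## with one worker) the batch runs sequentially, which satisfies the same
## contract trivially.
.runBatch <- function(indices, workFn, nWorkers) {
    safe <- function(k) tryCatch(list(ok = TRUE, value = workFn(k)),
                                 error = function(e)
                                     list(ok = FALSE, message = conditionMessage(e)))
    if (nWorkers > 1L && .Platform$OS.type == "unix") {
        parallel::mclapply(indices, safe, mc.cores = nWorkers,
                           mc.preschedule = FALSE)
    } else {
        lapply(indices, safe)
    }
}

#' Dispatch a permutation plan across the two-tier executor
#'
#' Every permutation index is processed exactly once; an idle worker
#' receives one not-yet-assigned index at a time (pull queue).  `workFn`
#' must be a pure function of the index returning the m-vector of
#' N-statistics; its result is stored in row k of the output regardless of
#' completion order.  A failing permutation aborts the dispatch, reporting
#' the failing index.  With `maxInFlight` set, at most that many
#' permutations are dispatched concurrently.
#'
#' @param plan a [PermutationPlan-class].
#' @param workFn function(k) returning the length-m statistic vector for
#'   permutation k.
#' @param config an [ExecutorConfig-class].
#' @return a [NullDistribution-class] (K x m).
#' @export
dispatch <- function(plan, workFn, config = executorConfig()) {
    validObject(config)
    K <- plan@K
    batchSize <- if (is.na(config@maxInFlight)) K else config@maxInFlight
    rowsDone <- vector("list", K)
    for (start in seq.int(1L, K, by = batchSize)) {
        idx <- seq.int(start, min(start + batchSize - 1L, K))
        res <- .runBatch(idx, workFn, config@nWorkers)
        for (j in seq_along(idx)) {
            r <- res[[j]]
            if (inherits(r, "try-error") || !isTRUE(r$ok))
                stop(sprintf("permutation %d failed: %s", idx[j],
                             if (is.list(r)) r$message else as.character(r)))
            if (!is.null(rowsDone[[idx[j]]]))
                stop(sprintf("internal error: duplicate completion for permutation %d",
                             idx[j]))
            rowsDone[[idx[j]]] <- r$value
        }
    }
    missing <- which(vapply(rowsDone, is.null, logical(1)))
    if (length(missing))
        stop("permutations never completed: ",
             paste(missing, collapse = ", "))
    stats <- do.call(rbind, rowsDone)
    dimnames(stats) <- NULL
    new("NullDistribution", stats = stats)
}
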