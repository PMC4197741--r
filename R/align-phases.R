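#' @include align-engine.R
NULL

#' Candidate seed nodes of a network
#'
#' The bootstrap phase only seeds alignments at nodes of network degree at
#' least `sigma`; higher values speed the search up at the cost of
#' accuracy, and values of 1-2 are recommended for sparse networks.
#'
#' @param network a [PPINetwork-class].
#' @param sigma non-negative integer minimum degree.
#' @return character vector of protein ids with degree >= sigma (possibly
#'   empty).
#' @examples
#' net <- PPINetwork("n", data.frame(from = c("A", "B"), to = c("B", "C")))
#' candidateSeedNodes(net, 2)   # "B"
#' @export
candidateSeedNodes <- function(network, sigma) {
    deg <- igraph::degree(interactionGraph(network))
    names(deg)[deg >= sigma]
}

#' Similarity score of one alignment row
#'
#' The seed objective: the sum of pairwise similarity scores over all
#' unordered network pairs of the row (shared-group counts in cog mode).
#'
#' @param row character vector of protein ids, one per network.
#' @param sim a [SimilarityStore-class].
#' @return a non-negative number.
#' @export
rowSimilarity <- function(row, sim) {
    row <- as.character(row)
    n <- length(row)
    s <- 0
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n))
        s <- s + pairScore(sim, row[i], row[j])
    s
}

.seedCandidates <- function(engine, sigma) {
    lapply(seq_len(engine$N), function(k)
        which(engine$degree[[k]] >= sigma))
}

.sampleSeedIdx <- function(engine, cand, iterSeed) {
    if (any(lengths(cand) == 0L)) return(NULL)
    SC <- .candScores(engine, cand)
    conn <- lapply(cand, function(cc) numeric(length(cc)))
    res <- .gibbsRow(SC, conn, iterSeed)
    idx <- vapply(seq_len(engine$N), function(k) cand[[k]][res$members[k]],
                  integer(1))
    list(idx = idx, score = res$score)
}

#' Gibbs-sample one seed row
#'
#' Bootstrap phase: starting from one uniformly drawn candidate per
#' network, the sampler cyclically resamples one network's member with
#' probability proportional to a small floor plus its total similarity to
#' the other fixed members, and returns the best-scoring row visited.
#' Sampling uses R's RNG stream; seed it (or use [alignNetworks()], which
#' does) for reproducibility.
#'
#' @param networks list of [PPINetwork-class] objects.
#' @param sim a [SimilarityStore-class].
#' @param config an [AlignmentConfig-class]; `iterSeed` and `sigma` are
#'   used.
#' @return named character vector (one protein per network), or `NULL`
#'   when some network has no candidate of degree >= sigma ("no seed
#'   found").
#' @export
gibbsSampleSeed <- function(networks, sim, config = alignmentConfig()) {
    engine <- .engineBuild(networks, sim)
    cand <- .seedCandidates(engine, config@sigma)
    res <- .sampleSeedIdx(engine, cand, config@iterSeed)
    if (is.null(res)) return(NULL)
    out <- vapply(seq_len(engine$N), function(k)
        engine$nodeNames[[k]][res$idx[k]], character(1))
    names(out) <- engine$ids
    out
}

#' Mean weighted density of the aligned subgraphs
#'
#' For each network the induced subgraph on that network's column is
#' scored as (sum of its edge weights) / (k choose 2), with `k` the number
#' of rows; the alignment's local density is the mean over networks, a
#' value in `[0, 1]`.  By convention it is 0 below two rows.
#'
#' @param alignment an [Alignment-class].
#' @param networks list of [PPINetwork-class] objects covering the
#'   alignment's network ids.
#' @return a number in `[0, 1]`.
#' @export
localDensity <- function(alignment, networks) {
    k <- nrow(alignment@rows)
    if (k < 2L) return(0)
    nets <- .netsByIds(networks, alignment@networks)
    mean(vapply(seq_along(nets), function(i) {
        g <- interactionGraph(nets[[i]])
        sg <- igraph::induced_subgraph(g, alignment@rows[, i])
        w <- igraph::E(sg)$weight
        sum(w) / choose(k, 2)
    }, numeric(1)))
}

# One extension attempt: per-network candidates are the unused neighbours
# of the current column; a new row is Gibbs-sampled with member weights
# eps + similarity to the tentative members + edge weight into the column.
# Returns NULL when any network has no candidates.
.sampleExtensionRowIdx <- function(engine, idxMat, iterExtend) {
    N <- engine$N
    cand <- vector("list", N)
    conn <- vector("list", N)
    for (k in seq_len(N)) {
        col <- idxMat[, k]
        nb <- engine$adj[[k]][, col, drop = FALSE]
        deg <- if (is.matrix(nb)) rowSums(nb != 0) else Matrix::rowSums(nb != 0)
        cc <- setdiff(which(deg > 0), col)
        if (length(cc) == 0L) return(NULL)
        cand[[k]] <- cc
        cw <- engine$adj[[k]][cc, col, drop = FALSE]
        conn[[k]] <- as.numeric(if (is.matrix(cw)) rowSums(cw)
                                else Matrix::rowSums(cw))
    }
    SC <- .candScores(engine, cand)
    res <- .gibbsRow(SC, conn, iterExtend)
    list(idx = vapply(seq_len(N), function(k) cand[[k]][res$members[k]],
                      integer(1)),
         score = res$score)
}

.extendIdx <- function(engine, idxMat, iterExtend) {
    trace <- numeric(0)
    repeat {
        step <- .sampleExtensionRowIdx(engine, idxMat, iterExtend)
        if (is.null(step)) break
        newMat <- rbind(idxMat, step$idx)
        if (.perRowDensity(engine, newMat) > .perRowDensity(engine, idxMat)) {
            idxMat <- newMat
            trace <- c(trace, .perRowDensity(engine, idxMat))
        } else break
    }
    list(idx = idxMat, trace = trace)
}

#' Greedy density-driven extension of an alignment
#'
#' Iterative phase: repeatedly Gibbs-sample one additional row from the
#' unused neighbours of the current aligned subgraphs, and keep it only
#' while it strictly increases the growth density of the alignment (the
#' mean per-row induced edge weight); otherwise revert and stop.  Column
#' injectivity is preserved because candidates exclude already-aligned
#' nodes.
#'
#' @inheritParams gibbsSampleSeed
#' @param alignment the [Alignment-class] to extend.
#' @return the extended [Alignment-class]; its `metadata$densityTrace`
#'   records the strictly increasing objective values of accepted steps.
#' @export
extendAlignment <- function(alignment, networks, sim,
                            config = alignmentConfig()) {
    engine <- .engineBuild(.netsByIds(networks, alignment@networks), sim)
    res <- .extendIdx(engine, .rowsToIdx(engine, alignment@rows),
                      config@iterExtend)
    Alignment(alignment@networks, .idxToRows(engine, res$idx),
              metadata = modifyList(alignment@metadata,
                                    list(densityTrace = res$trace)))
}

# Contribution of each row: its similarity plus its summed edge weights to
# the rest of its columns; the weakest row is swapped out first.
.rowContributions <- function(engine, idxMat) {
    k <- nrow(idxMat)
    vapply(seq_len(k), function(r) {
        s <- .rowSimilarityIdx(engine, idxMat[r, ])
        for (i in seq_len(engine$N))
            s <- s + sum(engine$adj[[i]][idxMat[r, i],
                                         idxMat[-r, i, drop = TRUE]])
        s
    }, numeric(1))
}

.refineObjective <- function(engine, idxMat)
    c(density = .perRowDensity(engine, idxMat),
      similarity = .totalSimilarity(engine, idxMat))

# Lexicographic "does not decrease": density first, total similarity as
# tie-break.
.objNotWorse <- function(a, b, tol = 1e-9) {
    if (a[1] > b[1] + tol) return(TRUE)
    if (a[1] < b[1] - tol) return(FALSE)
    a[2] >= b[2] - tol
}

.refineIdx <- function(engine, idxMat, refine, iterExtend) {
    trace <- numeric(0)
    for (it in seq_len(refine)) {
        if (nrow(idxMat) < 2L) break
        contrib <- .rowContributions(engine, idxMat)
        worst <- which.min(contrib)         # ties: lowest row index
        reduced <- idxMat[-worst, , drop = FALSE]
        swap <- .sampleExtensionRowIdx(engine, reduced, iterExtend)
        if (!is.null(swap)) {
            candMat <- rbind(reduced, swap$idx)
            if (.objNotWorse(.refineObjective(engine, candMat),
                             .refineObjective(engine, idxMat)))
                idxMat <- candMat
        }
        trace <- c(trace, .perRowDensity(engine, idxMat))
    }
    list(idx = idxMat, trace = trace)
}

#' Iterative refinement of an alignment
#'
#' Refinement phase: for `refine` iterations the row with the lowest
#' contribution (similarity plus intra-column connectivity) is removed and
#' one replacement row is Gibbs-sampled from the remaining subgraphs'
#' neighbours; the swap is kept only when the objective (growth density,
#' ties broken by total row similarity) does not decrease.  With
#' `refine = 0` the alignment is returned unchanged.
#'
#' @inheritParams extendAlignment
#' @return the refined [Alignment-class]; `metadata$refineTrace` records
#'   the non-decreasing objective after each iteration.
#' @export
refineAlignment <- function(alignment, networks, sim,
                            config = alignmentConfig()) {
    engine <- .engineBuild(.netsByIds(networks, alignment@networks), sim)
    res <- .refineIdx(engine, .rowsToIdx(engine, alignment@rows),
                      config@refine, config@iterExtend)
    Alignment(alignment@networks, .idxToRows(engine, res$idx),
              metadata = modifyList(alignment@metadata,
                                    list(refineTrace = res$trace)))
}

#' Multiple local alignment of PPI networks
#'
#' Full pipeline: for each of `restarts` attempts a seed row is
#' Gibbs-sampled (bootstrap phase), extended greedily while the aligned
#' subgraphs grow denser (iterative phase) and refined by node swaps
#' (refinement phase).  The collected alignments are then filtered to the
#' minimum complex size, deduplicated by node overlap, and sorted by size
#' then structural conservation.  The run is deterministic for a fixed
#' `config@seed`.
#'
#' @param networks list of two or more [PPINetwork-class] objects with
#'   unique ids.
#' @param sim a [SimilarityStore-class] covering cross-network pairs.
#' @param config an [AlignmentConfig-class].
#' @param verbose emit one progress message per restart.
#' @return list of [Alignment-class] objects, sorted by decreasing size
#'   then decreasing ISC; each carries `metadata` with `density` (the
#'   normalized [localDensity()]), `isc`, `seedScore`, `densityTrace`,
#'   `refineTrace` and `restart`.
#' @examples
#' fx <- generateFixture(fixtureSpec(backgroundNodes = 30, seed = 1,
#'     complexes = list(list(size = 5, q = 0.95, wMin = 0.7, wMax = 1))))
#' res <- alignNetworks(fx$networks, fx$similarity,
#'     alignmentConfig(sigma = 2, restarts = 10, seed = 1))
#' res[[1]]
#' @export
alignNetworks <- function(networks, sim, config = alignmentConfig(),
                          verbose = FALSE) {
    if (length(networks) < 2L)
        stop("at least two networks are required", call. = FALSE)
    engine <- .engineBuild(networks, sim)
    cand <- .seedCandidates(engine, config@sigma)
    restarts <- config@restarts
    if (is.na(restarts)) {
        smallest <- which.min(engine$ns)
        restarts <- max(1L, min(100L, length(cand[[smallest]])))
    }
    old <- .pushSeed(config@seed)
    on.exit(.popSeed(old), add = TRUE)

    results <- list()
    for (r in seq_len(restarts)) {
        seed <- .sampleSeedIdx(engine, cand, config@iterSeed)
        if (is.null(seed)) break        # no candidates: retrying cannot help
        ext <- .extendIdx(engine, matrix(seed$idx, nrow = 1L),
                          config@iterExtend)
        ref <- .refineIdx(engine, ext$idx, config@refine, config@iterExtend)
        aln <- Alignment(engine$ids, .idxToRows(engine, ref$idx),
                         metadata = list(seedScore = seed$score,
                                         densityTrace = ext$trace,
                                         refineTrace = ref$trace,
                                         restart = r))
        if (verbose)
            message(sprintf(
                "restart %d: seed score %.2f, %d extension step(s), %d rows",
                r, seed$score, length(ext$trace), nrow(ref$idx)))
        results[[length(results) + 1L]] <- aln
    }
    if (length(results) == 0L)
        stop("no seed found: no network node reaches degree sigma = ",
             config@sigma, call. = FALSE)

    results <- filterBySize(results, config@minComplexSize)
    for (i in seq_along(results)) {
        idx <- .rowsToIdx(engine, results[[i]]@rows)
        results[[i]]@metadata$density <- .normDensity(engine, idx)
        results[[i]]@metadata$isc <- .iscFromEngine(engine, idx)
    }
    sizes <- vapply(results, alignmentSize, integer(1))
    iscs <- vapply(results, function(a) a@metadata$isc, numeric(1))
    results <- results[order(-sizes, -iscs)]
    filterByOverlap(results, config@overlap)
}

# Save/seed/restore the global RNG state so runs are reproducible without
# clobbering the caller's stream.
.pushSeed <- function(seed) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed)
    old
}

.popSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
}
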