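#' @include io-annotations.R
NULL

# Internal alignment engine.
#
# All phase computations run on integer node indices against precomputed
# per-network adjacency matrices and per-network-pair cross-similarity
# matrices.  Matrices are kept dense below .DENSE_LIMIT nodes (fast column
# slicing inside the Gibbs scans) and sparse (dgCMatrix) above it.

.DENSE_LIMIT <- 1500L
.GIBBS_EPS <- 1e-6    # additive floor of the Gibbs conditionals

.engineBuild <- function(networks, sim) {
    ids <- vapply(networks, networkId, character(1))
    if (anyDuplicated(ids))
        stop("network ids must be unique: ", paste(ids, collapse = ", "),
             call. = FALSE)
    graphs <- lapply(networks, interactionGraph)
    nodeNames <- lapply(graphs, function(g) igraph::V(g)$name)
    ns <- lengths(nodeNames)
    dense <- max(ns) <= .DENSE_LIMIT
    adj <- lapply(graphs, function(g) {
        a <- igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g) > 0)
            "weight" else NULL, sparse = TRUE)
        a <- methods::as(a, "generalMatrix")
        if (dense) as.matrix(a) else a
    })
    S <- .crossScoreMatrices(sim, nodeNames, dense)
    list(ids = ids, graphs = graphs, nodeNames = nodeNames, ns = ns,
         adj = adj, S = S, N = length(networks),
         degree = lapply(graphs, igraph::degree))
}

# S[[i]][[j]] for all i != j: score matrix n_i x n_j (S[[j]][[i]] is its
# transpose, materialised once so slicing stays cheap).
.crossScoreMatrices <- function(sim, nodeNames, dense) {
    N <- length(nodeNames)
    S <- rep(list(vector("list", N)), N)
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
        if (sim@mode == "bitscore") {
            p <- sim@pairs
            i1 <- match(p$p1, nodeNames[[i]]); j1 <- match(p$p2, nodeNames[[j]])
            i2 <- match(p$p2, nodeNames[[i]]); j2 <- match(p$p1, nodeNames[[j]])
            rows <- c(i1, i2); cols <- c(j1, j2); vals <- c(p$score, p$score)
            keep <- !is.na(rows) & !is.na(cols)
            rows <- rows[keep]; cols <- cols[keep]; vals <- vals[keep]
            if (length(rows)) {
                # self-pairs (p1 == p2 across twin networks) appear twice
                key <- paste(rows, cols)
                first <- !duplicated(key)
                rows <- rows[first]; cols <- cols[first]; vals <- vals[first]
            }
            M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                                      dims = c(length(nodeNames[[i]]),
                                               length(nodeNames[[j]])))
        } else {
            allGroups <- unique(unlist(sim@groups, use.names = FALSE))
            inc <- function(nn) {
                ii <- integer(); jj <- integer()
                for (k in seq_along(nn)) {
                    g <- sim@groups[[nn[k]]]
                    if (!is.null(g)) {
                        gi <- match(g, allGroups)
                        ii <- c(ii, rep.int(k, length(gi))); jj <- c(jj, gi)
                    }
                }
                Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                                     dims = c(length(nn),
                                              max(1L, length(allGroups))))
            }
            M <- inc(nodeNames[[i]]) %*% Matrix::t(inc(nodeNames[[j]]))
            M <- methods::as(M, "generalMatrix")
        }
        if (dense) M <- as.matrix(M)
        S[[i]][[j]] <- M
        S[[j]][[i]] <- if (dense) t(M) else Matrix::t(M)
    }
    S
}

# Dense candidate-restricted score matrices SC[[k]][[j]]:
# |cand_k| x |cand_j| blocks used inside a Gibbs scan.
.candScores <- function(engine, cand) {
    N <- engine$N
    SC <- rep(list(vector("list", N)), N)
    for (k in seq_len(N)) for (j in seq_len(N)) {
        if (j == k) next
        SC[[k]][[j]] <- as.matrix(engine$S[[k]][[j]][cand[[k]], cand[[j]],
                                                     drop = FALSE])
    }
    SC
}

# Cyclic-scan Gibbs sampler over one alignment row.  One member per
# network, initialised uniformly over candidates; each sweep resamples the
# current network's member with probability proportional to
# eps + similarity to the other fixed members + connectivity bonus.
# Returns the best row visited, scored by similarity + connectivity.
.gibbsRow <- function(SC, conn, iters, eps = .GIBBS_EPS) {
    N <- length(conn)
    sizes <- lengths(conn)
    m <- vapply(sizes, function(s) sample.int(s, 1L), integer(1))
    obj <- function(m) {
        s <- 0
        for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N))
            s <- s + SC[[i]][[j]][m[i], m[j]]
        for (k in seq_len(N)) s <- s + conn[[k]][m[k]]
        s
    }
    best <- m
    bestScore <- obj(m)
    for (t in seq_len(iters)) {
        k <- (t - 1L) %% N + 1L
        w <- conn[[k]] + eps
        for (j in seq_len(N)[-k])
            w <- w + SC[[k]][[j]][, m[j]]
        m[k] <- sample.int(sizes[k], 1L, prob = w)
        s <- obj(m)
        if (s > bestScore) {
            bestScore <- s
            best <- m
        }
    }
    # greedy polish: iterated conditional modes from the best visited row,
    # so single-coordinate near-misses of the stochastic scan are repaired
    # deterministically
    m <- best
    repeat {
        improved <- FALSE
        for (k in seq_len(N)) {
            w <- conn[[k]]
            for (j in seq_len(N)[-k])
                w <- w + SC[[k]][[j]][, m[j]]
            b <- which.max(w)
            if (w[b] > w[m[k]] + 1e-12) {
                m[k] <- b
                improved <- TRUE
            }
        }
        if (!improved) break
    }
    s <- obj(m)
    if (s > bestScore) {
        bestScore <- s
        best <- m
    }
    list(members = best, score = bestScore)
}

# Growth objective of the extension/refinement phases: mean over networks
# of (sum of induced edge weights) / (number of rows) -- the weighted
# densest-subgraph density, strictly increasing along accepted extension
# steps of a growing dense complex.
.perRowDensity <- function(engine, idxMat) {
    k <- nrow(idxMat)
    if (k < 1L) return(0)
    mean(vapply(seq_len(engine$N), function(i) {
        sum(engine$adj[[i]][idxMat[, i], idxMat[, i]]) / 2 / k
    }, numeric(1)))
}

# Reported subgraph density: mean over networks of
# (sum of induced edge weights) / choose(k, 2), in [0, 1]; 0 below 2 rows.
.normDensity <- function(engine, idxMat) {
    k <- nrow(idxMat)
    if (k < 2L) return(0)
    mean(vapply(seq_len(engine$N), function(i) {
        sum(engine$adj[[i]][idxMat[, i], idxMat[, i]]) / 2 / choose(k, 2)
    }, numeric(1)))
}

# Total cross-network similarity of all rows.
.totalSimilarity <- function(engine, idxMat) {
    s <- 0
    N <- engine$N
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N))
        s <- s + sum(engine$S[[i]][[j]][cbind(idxMat[, i], idxMat[, j])])
    as.numeric(s)
}

# Similarity of a single row (integer node indices).
.rowSimilarityIdx <- function(engine, idx) {
    s <- 0
    N <- engine$N
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N))
        s <- s + engine$S[[i]][[j]][idx[i], idx[j]]
    as.numeric(s)
}

.rowsToIdx <- function(engine, rows) {
    idx <- vapply(seq_len(engine$N), function(k) {
        i <- match(rows[, k], engine$nodeNames[[k]])
        if (anyNA(i))
            stop("alignment row member not found in network '",
                 engine$ids[k], "'", call. = FALSE)
        i
    }, integer(nrow(rows)))
    matrix(idx, nrow = nrow(rows))
}

.idxToRows <- function(engine, idxMat) {
    out <- vapply(seq_len(engine$N), function(k)
        engine$nodeNames[[k]][idxMat[, k]], character(nrow(idxMat)))
    out <- matrix(out, nrow = nrow(idxMat))
    colnames(out) <- engine$ids
    out
}

.netsByIds <- function(networks, ids) {
    nid <- vapply(networks, networkId, character(1))
    pos <- match(ids, nid)
    if (anyNA(pos))
        stop("missing network(s): ", paste(ids[is.na(pos)], collapse = ", "),
             call. = FALSE)
    networks[pos]
}
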