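# Builders for small deterministic fixtures and independent brute-force
# oracles.  Oracles deliberately use per-pair igraph queries and explicit
# loops, not the package's matrix algebra.

cliqueNetwork <- function(id, nodeNames, weight = 1) {
    cp <- utils::combn(nodeNames, 2)
    PPINetwork(id, data.frame(from = cp[1, ], to = cp[2, ],
                              weight = weight, stringsAsFactors = FALSE))
}

pathNetwork <- function(id, nodeNames, weight = 1) {
    n <- length(nodeNames)
    PPINetwork(id, data.frame(from = nodeNames[-n], to = nodeNames[-1],
                              weight = weight, stringsAsFactors = FALSE))
}

# Identity bit scores between same-named proteins of different networks.
identityBitScores <- function(nodeNames, score = 100) {
    bitScoreStore(data.frame(p1 = nodeNames, p2 = nodeNames, score = score,
                             stringsAsFactors = FALSE))
}

# Random networks plus a random (not planted) alignment over them.
randomAlignmentCase <- function(nNet, nRows, nNodes = 8, p = 0.4) {
    ids <- paste0("net", seq_len(nNet))
    networks <- lapply(seq_len(nNet), function(i) {
        nm <- paste0("x", i, "_", seq_len(nNodes))
        cp <- utils::combn(nm, 2)
        on <- stats::runif(ncol(cp)) < p
        PPINetwork(ids[i],
                   data.frame(from = cp[1, on], to = cp[2, on],
                              weight = stats::runif(sum(on)),
                              stringsAsFactors = FALSE),
                   nodes = nm)
    })
    rows <- vapply(seq_len(nNet), function(i)
        sample(nodes(networks[[i]]), nRows), character(nRows))
    list(networks = networks,
         alignment = Alignment(ids, matrix(rows, nrow = nRows)))
}

# Brute-force ISC: per network pair, count conserved edges by querying
# igraph adjacency row pair by row pair.
oracleISC <- function(alignment, networks) {
    rows <- alignmentRows(alignment)
    k <- nrow(rows)
    if (k < 2) return(0)
    ids <- alignedNetworks(alignment)
    nets <- networks[match(ids, vapply(networks, networkId, ""))]
    N <- length(nets)
    scores <- c()
    for (i in seq_len(N - 1)) for (j in seq(i + 1, N)) {
        gi <- interactionGraph(nets[[i]])
        gj <- interactionGraph(nets[[j]])
        ei <- 0; ej <- 0; cons <- 0
        for (r1 in seq_len(k - 1)) for (r2 in seq(r1 + 1, k)) {
            ai <- igraph::are_adjacent(gi, rows[r1, i], rows[r2, i])
            aj <- igraph::are_adjacent(gj, rows[r1, j], rows[r2, j])
            ei <- ei + ai; ej <- ej + aj
            if (ai && aj) cons <- cons + 1
        }
        scores <- c(scores, if (ei + ej == 0) 1 else 2 * cons / (ei + ej))
    }
    100 * mean(scores)
}

# Brute-force local density: explicit loop over row pairs.
oracleDensity <- function(alignment, networks) {
    rows <- alignmentRows(alignment)
    k <- nrow(rows)
    if (k < 2) return(0)
    ids <- alignedNetworks(alignment)
    nets <- networks[match(ids, vapply(networks, networkId, ""))]
    dens <- c()
    for (i in seq_along(nets)) {
        g <- interactionGraph(nets[[i]])
        s <- 0
        for (r1 in seq_len(k - 1)) for (r2 in seq(r1 + 1, k)) {
            if (igraph::are_adjacent(g, rows[r1, i], rows[r2, i])) {
                eid <- igraph::get_edge_ids(g, c(rows[r1, i], rows[r2, i]))
                s <- s + igraph::E(g)$weight[eid]
            }
        }
        dens <- c(dens, s / choose(k, 2))
    }
    mean(dens)
}

# Brute-force overlap filter: eliminate, to a fixed point, the smaller
# member of the worst surviving conflict (priority to conflicts whose
# larger member is biggest; ties by discovery order).
oracleOverlapFilter <- function(alignments, theta) {
    n <- length(alignments)
    alive <- rep(TRUE, n)
    sizes <- vapply(alignments, alignmentSize, integer(1))
    repeat {
        best <- NULL
        for (a in seq_len(n)) for (b in seq_len(n)) {
            if (a == b || !alive[a] || !alive[b]) next
            if (sizes[a] < sizes[b] ||
                (sizes[a] == sizes[b] && a > b)) next   # a: larger/earlier
            if (overlapFraction(alignments[[a]], alignments[[b]]) <= theta)
                next
            if (is.null(best) ||
                sizes[a] > sizes[best[1]] ||
                (sizes[a] == sizes[best[1]] &&
                 (a < best[1] || (a == best[1] && b < best[2]))))
                best <- c(a, b)
        }
        if (is.null(best)) break
        alive[best[2]] <- FALSE
    }
    alignments[alive]
}

rowKeys <- function(alignment, netOrder = NULL) {
    rows <- alignmentRows(alignment)
    if (!is.null(netOrder))
        rows <- rows[, match(netOrder, alignedNetworks(alignment)),
                     drop = FALSE]
    sort(apply(rows, 1, paste, collapse = "\t"))
}

sameAlignmentSets <- function(x, y) {
    kx <- sort(vapply(x, function(a) paste(rowKeys(a), collapse = "|"), ""))
    ky <- sort(vapply(y, function(a) paste(rowKeys(a), collapse = "|"), ""))
    identical(kx, ky)
}

# Exhaustive best seed row by enumerating every candidate combination.
bruteBestSeed <- function(networks, sim, sigma) {
    cands <- lapply(networks, candidateSeedNodes, sigma = sigma)
    grid <- expand.grid(cands, stringsAsFactors = FALSE)
    scores <- apply(grid, 1, function(r) rowSimilarity(unlist(r), sim))
    unname(unlist(grid[which.max(scores), ]))
}

# Small seed-search instance: three 5-cliques with continuous random
# cross-network scores (unique optimum almost surely).
smallSeedInstance <- function() {
    ids <- c("sa", "sb", "sc")
    networks <- lapply(seq_along(ids), function(i)
        cliqueNetwork(ids[i], paste0("s", i, "_", 1:5), weight = 0.5))
    prs <- list()
    for (i in 1:2) for (j in seq(i + 1, 3)) {
        g <- expand.grid(p1 = nodes(networks[[i]]), p2 = nodes(networks[[j]]),
                         stringsAsFactors = FALSE)
        g$score <- stats::runif(nrow(g), 0, 10)
        prs[[length(prs) + 1]] <- g
    }
    list(networks = networks, sim = bitScoreStore(do.call(rbind, prs)))
}
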