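#' @include io-alignment.R
NULL

#' Specify a synthetic alignment benchmark
#'
#' The defaults describe the package's reference study conditions: three
#' networks of 60 proteins, sparse Erdos-Renyi background (edge
#' probability 0.05, weights uniform in `[0.1, 0.5]`), two planted
#' conserved complexes of six proteins wired with probability 0.9 at
#' weights in `[0.7, 1.0]`, counterpart bit score 200 against decoy
#' scores at most 20.  Background and planted weight bands deliberately
#' occupy the low and high thirds of `[0, 1]`, so planted interactions
#' also separate from background in the alignment-graph colour classes.
#'
#' @param nNetworks number of networks.
#' @param backgroundNodes proteins per network (planted nodes included).
#' @param backgroundEdgeProb Erdos-Renyi background edge probability.
#' @param complexes list of plantings; each a list with `size`, `q`
#'   (intra-complex edge probability), `wMin` and `wMax`.
#' @param plantedSim bit score of counterpart pairs.
#' @param decoySimRange range of random decoy bit scores.
#' @param decoysPerPair decoy pairs drawn per network pair.
#' @param seed generator RNG seed.
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(nNetworks = 3L, backgroundNodes = 60L,
                        backgroundEdgeProb = 0.05,
                        complexes = list(
                            list(size = 6L, q = 0.9, wMin = 0.7, wMax = 1.0),
                            list(size = 6L, q = 0.9, wMin = 0.7, wMax = 1.0)),
                        plantedSim = 200, decoySimRange = c(0, 20),
                        decoysPerPair = 60L, seed = 1L) {
    new("FixtureSpec", nNetworks = as.integer(nNetworks),
        backgroundNodes = as.integer(backgroundNodes),
        backgroundEdgeProb = as.numeric(backgroundEdgeProb),
        complexes = complexes, plantedSim = as.numeric(plantedSim),
        decoySimRange = as.numeric(decoySimRange),
        decoysPerPair = as.integer(decoysPerPair), seed = as.integer(seed))
}

#' Generate a synthetic benchmark with planted conserved complexes
#'
#' Builds `nNetworks` random background networks and plants, in each, the
#' complexes of the spec: per complex `c` and member `k`, the node
#' `C<c>_N<i>_P<k>` of network `i` (counterpart naming makes the ground
#' truth self-describing).  Counterpart nodes across networks receive bit
#' score `plantedSim`; random cross-network decoy pairs receive scores in
#' `decoySimRange`.  An orthology-group store (one group per ground-truth
#' row plus decoy groups) and a decorative GO annotation store are
#' generated alongside.  The output is deterministic given `spec@seed`,
#' and the caller's RNG stream is left untouched.
#'
#' @param spec a [FixtureSpec-class].
#' @return a list with elements `networks` (list of [PPINetwork-class]),
#'   `similarity` ([SimilarityStore-class], bitscore mode),
#'   `cogSimilarity` ([SimilarityStore-class], cog mode), `annotations`
#'   ([AnnotationStore-class]) and `truth` (character matrix of planted
#'   rows, one column per network).
#' @export
generateFixture <- function(spec) {
    methods::validObject(spec)
    old <- .pushSeed(spec@seed)
    on.exit(.popSeed(old), add = TRUE)

    N <- spec@nNetworks
    n <- spec@backgroundNodes
    sizes <- vapply(spec@complexes, function(cx) as.integer(cx$size),
                    integer(1))
    nPlanted <- sum(sizes)

    nameNodes <- function(i) {
        planted <- unlist(lapply(seq_along(sizes), function(cx)
            sprintf("C%d_N%d_P%d", cx, i, seq_len(sizes[cx]))))
        bg <- if (n > nPlanted)
            sprintf("N%d_B%03d", i, seq_len(n - nPlanted)) else character()
        c(planted, bg)
    }

    networks <- vector("list", N)
    for (i in seq_len(N)) {
        nm <- nameNodes(i)
        pairs <- utils::combn(n, 2)
        on <- runif(ncol(pairs)) < spec@backgroundEdgeProb
        edges <- data.frame(
            from = nm[pairs[1, on]], to = nm[pairs[2, on]],
            weight = runif(sum(on), 0.1, 0.5), stringsAsFactors = FALSE)
        offset <- 0L
        for (cx in seq_along(sizes)) {
            members <- nm[offset + seq_len(sizes[cx])]
            q <- spec@complexes[[cx]]$q
            wMin <- spec@complexes[[cx]]$wMin
            wMax <- spec@complexes[[cx]]$wMax
            cp <- utils::combn(members, 2)
            keep <- runif(ncol(cp)) < q
            if (any(keep)) {
                planted <- data.frame(
                    from = cp[1, keep], to = cp[2, keep],
                    weight = runif(sum(keep), wMin, wMax),
                    stringsAsFactors = FALSE)
                # planted wiring replaces any background edge on the pair
                bgKey <- paste(pmin(edges$from, edges$to),
                               pmax(edges$from, edges$to))
                plKey <- paste(pmin(planted$from, planted$to),
                               pmax(planted$from, planted$to))
                edges <- rbind(edges[!(bgKey %in% plKey), , drop = FALSE],
                               planted)
            }
            offset <- offset + sizes[cx]
        }
        networks[[i]] <- PPINetwork(sprintf("net%d", i), edges, nodes = nm)
    }

    truth <- NULL
    for (cx in seq_along(sizes))
        truth <- rbind(truth, vapply(seq_len(N), function(i)
            sprintf("C%d_N%d_P%d", cx, i, seq_len(sizes[cx])),
            character(sizes[cx])))
    if (is.null(truth)) truth <- matrix(character(), 0, N)
    colnames(truth) <- sprintf("net%d", seq_len(N))

    # bit scores: counterpart pairs at plantedSim, decoys at decoy levels
    simRows <- list()
    allNames <- lapply(seq_len(N), nameNodes)
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
        if (nrow(truth) > 0)
            simRows[[length(simRows) + 1L]] <- data.frame(
                p1 = truth[, i], p2 = truth[, j], score = spec@plantedSim,
                stringsAsFactors = FALSE)
        if (spec@decoysPerPair > 0L) {
            d1 <- sample(allNames[[i]], spec@decoysPerPair, replace = TRUE)
            d2 <- sample(allNames[[j]], spec@decoysPerPair, replace = TRUE)
            truthKey <- if (nrow(truth) > 0)
                paste(truth[, i], truth[, j]) else character()
            keep <- !(paste(d1, d2) %in% truthKey) & !duplicated(paste(d1, d2))
            simRows[[length(simRows) + 1L]] <- data.frame(
                p1 = d1[keep], p2 = d2[keep],
                score = runif(sum(keep), spec@decoySimRange[1],
                              spec@decoySimRange[2]),
                stringsAsFactors = FALSE)
        }
    }
    sim <- bitScoreStore(do.call(rbind, c(simRows,
        list(data.frame(p1 = character(), p2 = character(),
                        score = numeric(), stringsAsFactors = FALSE)))))

    # cog dialect: one orthology group per ground-truth row + decoy groups
    membership <- list()
    if (nrow(truth) > 0)
        for (r in seq_len(nrow(truth)))
            for (p in truth[r, ])
                membership[[p]] <- c(membership[[p]],
                                     sprintf("COG%04d", r))
    nDecoyGroups <- max(0L, spec@decoysPerPair %/% 10L)
    for (d in seq_len(nDecoyGroups)) {
        grp <- sprintf("NOG%04d", d)
        for (i in seq_len(N)) {
            p <- sample(allNames[[i]], 1L)
            membership[[p]] <- c(membership[[p]], grp)
        }
    }
    cogSim <- cogStore(membership)

    # decorative annotations for planted members and a few background nodes
    descs <- character(); terms <- list()
    goPool <- names(.GO_NAMESPACE)
    if (nrow(truth) > 0) {
        for (r in seq_len(nrow(truth))) {
            cxId <- sub("^C([0-9]+)_.*$", "\\1", truth[r, 1])
            for (p in truth[r, ]) {
                descs[p] <- sprintf("synthetic planted complex %s member", cxId)
                t <- list(cc = character(), bp = character(),
                          mf = character(), unclassified = character())
                for (term in sample(goPool, 2L))
                    t[[unname(.GO_NAMESPACE[term])]] <-
                        c(t[[unname(.GO_NAMESPACE[term])]], term)
                terms[[p]] <- t
            }
        }
    }
    ann <- annotationStore(descriptions = descs, terms = terms)

    list(networks = networks, similarity = sim, cogSimilarity = cogSim,
         annotations = ann, truth = truth)
}

#' Write fixture files in the package's input dialects
#'
#' Serialises a generated fixture as the exact file formats the readers
#' consume: one edge-list file per network, a bit-score file, an
#' orthology-group file, a GO annotation file, and the ground truth as a
#' tab-separated table.  Fixtures thereby double as format documentation.
#'
#' @param fixture result of [generateFixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixtureFiles <- function(fixture, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c()
    for (net in fixture$networks) {
        p <- file.path(dir, paste0(networkId(net), ".txt"))
        writeNetwork(net, p)
        paths[paste0("network.", networkId(net))] <- p
    }
    paths["bitscores"] <- writeBitScores(fixture$similarity,
                                         file.path(dir, "bitscores.tsv"))
    paths["cogs"] <- writeCogGroups(fixture$cogSimilarity,
                                    file.path(dir, "cogs.txt"))
    paths["annotations"] <- writeAnnotations(fixture$annotations,
                                             file.path(dir, "go.txt"))
    truthPath <- file.path(dir, "truth.tsv")
    utils::write.table(fixture$truth, truthPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths["truth"] <- truthPath
    invisible(paths)
}

#' Precision and recall of planted-row recovery
#'
#' A ground-truth row counts as recovered when some result alignment
#' contains it exactly (same proteins in the same network columns).
#' Recall is the fraction of truth rows recovered; precision is the
#' fraction of all result rows that match a truth row.
#'
#' @param result list of [Alignment-class] objects.
#' @param truth character matrix of planted rows (as in
#'   [generateFixture()]), columns named by network id.
#' @return list with `recall`, `precision`, `recovered`, `totalTruth`,
#'   `matchedRows`, `totalRows`.
#' @export
scoreRecovery <- function(result, truth) {
    nets <- colnames(truth)
    truthKeys <- if (nrow(truth) > 0)
        apply(truth, 1, paste, collapse = "\t") else character()
    resultKeys <- unlist(lapply(result, function(a) {
        cols <- match(nets, a@networks)
        if (anyNA(cols))
            stop("result and truth cover different networks", call. = FALSE)
        apply(a@rows[, cols, drop = FALSE], 1, paste, collapse = "\t")
    }))
    if (is.null(resultKeys)) resultKeys <- character()
    recovered <- sum(truthKeys %in% resultKeys)
    matched <- sum(resultKeys %in% truthKeys)
    list(recall = if (length(truthKeys)) recovered / length(truthKeys) else NA,
         precision = if (length(resultKeys)) matched / length(resultKeys)
                     else NA,
         recovered = recovered, totalTruth = length(truthKeys),
         matchedRows = matched, totalRows = length(resultKeys))
}
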