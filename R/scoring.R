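#' @include align-phases.R
NULL

# Boolean adjacency of each network's induced subgraph, rows/cols in
# alignment-row order, so that edge (r1, r2) is comparable across
# networks through the row correspondence.
.rowAdjacency <- function(engine, idxMat) {
    lapply(seq_len(engine$N), function(i) {
        a <- engine$adj[[i]][idxMat[, i], idxMat[, i], drop = FALSE]
        as.matrix(a) != 0
    })
}

.iscFromEngine <- function(engine, idxMat) {
    k <- nrow(idxMat)
    if (k < 2L) return(0)
    A <- .rowAdjacency(engine, idxMat)
    up <- upper.tri(A[[1]])
    N <- engine$N
    scores <- numeric(0)
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
        ei <- sum(A[[i]][up]); ej <- sum(A[[j]][up])
        conserved <- sum(A[[i]][up] & A[[j]][up])
        scores <- c(scores,
                    if (ei + ej == 0) 1 else 2 * conserved / (ei + ej))
    }
    100 * mean(scores)
}

#' Index of Structural Conservation (ISC)
#'
#' Measures the average degree of structural conservation of an alignment
#' as a percentage.  For every unordered network pair the edges of one
#' induced subgraph are mapped through the row correspondence into the
#' other; with `E_i`, `E_j` the induced edge sets and `C_ij` the edges
#' present on both sides, the pair score is the Dice ratio
#' `2 |C_ij| / (|E_i| + |E_j|)` (defined as 1 when both sets are empty),
#' and ISC is 100 times the mean over network pairs.  Edge presence, not
#' weight, is counted.
#'
#' @inheritParams localDensity
#' @return a percentage in `[0, 100]`; 0 by convention below two rows.
#' @export
iscScore <- function(alignment, networks) {
    nets <- .netsByIds(networks, alignment@networks)
    k <- nrow(alignment@rows)
    if (k < 2L) return(0)
    A <- lapply(seq_along(nets), function(i) {
        g <- interactionGraph(nets[[i]])
        col <- alignment@rows[, i]
        m <- igraph::as_adjacency_matrix(igraph::induced_subgraph(g, col),
                                         sparse = FALSE)
        m <- m[col, col, drop = FALSE]   # row order, not vertex order
        m != 0
    })
    up <- upper.tri(A[[1]])
    N <- length(nets)
    scores <- numeric(0)
    for (i in seq_len(N - 1L)) for (j in seq.int(i + 1L, N)) {
        ei <- sum(A[[i]][up]); ej <- sum(A[[j]][up])
        conserved <- sum(A[[i]][up] & A[[j]][up])
        scores <- c(scores,
                    if (ei + ej == 0) 1 else 2 * conserved / (ei + ej))
    }
    100 * mean(scores)
}

#' Fraction of shared nodes between two alignments
#'
#' The number of shared (network, protein) nodes divided by the total
#' node count of the smaller alignment (fewer rows; every alignment of
#' `r` rows over `N` networks has `r * N` nodes).
#'
#' @param a,b [Alignment-class] objects over the same networks.
#' @return a fraction in `[0, 1]`.
#' @export
overlapFraction <- function(a, b) {
    if (!setequal(a@networks, b@networks))
        stop("alignments cover different networks", call. = FALSE)
    bCols <- match(a@networks, b@networks)
    shared <- sum(vapply(seq_along(a@networks), function(k)
        length(intersect(a@rows[, k], b@rows[, bCols[k]])), integer(1)))
    denom <- min(nrow(a@rows), nrow(b@rows)) * length(a@networks)
    shared / denom
}

#' Discard heavily overlapping alignments
#'
#' Alignments are processed in order of decreasing size (ties keep
#' discovery order); each is kept only if its [overlapFraction()] with
#' every already-kept alignment is at most `overlap`.  When two
#' alignments share too many nodes, the smaller one is therefore the one
#' discarded.
#'
#' @param alignments list of [Alignment-class] objects.
#' @param overlap maximum allowed shared-node fraction in `[0, 1]`.
#' @return the surviving alignments, in decreasing-size order.
#' @export
filterByOverlap <- function(alignments, overlap) {
    stopifnot(overlap >= 0, overlap <= 1)
    if (length(alignments) == 0) return(alignments)
    ord <- order(-vapply(alignments, alignmentSize, integer(1)))
    kept <- list()
    for (a in alignments[ord]) {
        ok <- all(vapply(kept, function(k) overlapFraction(a, k) <= overlap,
                         logical(1)))
        if (ok) kept[[length(kept) + 1L]] <- a
    }
    kept
}

#' Enforce the minimum conserved-complex size
#'
#' @param alignments list of [Alignment-class] objects.
#' @param minComplexSize minimum number of rows.
#' @return the alignments with at least `minComplexSize` rows, in input
#'   order.
#' @export
filterBySize <- function(alignments, minComplexSize) {
    stopifnot(minComplexSize >= 1)
    Filter(function(a) alignmentSize(a) >= minComplexSize, alignments)
}

.weightColor <- function(w)
    ifelse(w < 1 / 3, "green", ifelse(w < 2 / 3, "yellow", "red"))

#' Build the merged alignment graph of one alignment
#'
#' Joins the induced subgraphs of all networks into one exportable model:
#' intra-edges are the within-network interactions, solid and
#' colour-classed by weight band (`p < 1/3` green, `1/3 <= p < 2/3`
#' yellow, `p >= 2/3` red); inter-edges link the `N` members of each
#' alignment row across networks (one per network pair, dashed).  Node
#' ids are `network::protein`.  Annotations, when given, decorate the
#' nodes and nothing else.
#'
#' @inheritParams localDensity
#' @param annotations optional [AnnotationStore-class].
#' @return an [AlignmentGraph-class].
#' @export
buildAlignmentGraph <- function(alignment, networks, annotations = NULL) {
    nets <- .netsByIds(networks, alignment@networks)
    N <- length(nets)
    k <- nrow(alignment@rows)

    nodeNet <- rep(alignment@networks, each = k)
    nodeProt <- as.vector(alignment@rows)
    nid <- paste0(nodeNet, "::", nodeProt)
    desc <- rep(NA_character_, length(nid))
    go <- rep("", length(nid))
    if (!is.null(annotations)) {
        d <- descriptions(annotations)[nodeProt]
        desc <- ifelse(is.na(d), NA_character_, unname(d))
        go <- vapply(nodeProt, function(p) {
            t <- goTerms(annotations, p)
            paste(unlist(t, use.names = FALSE), collapse = ";")
        }, character(1))
    }
    nodesDf <- data.frame(id = nid, network = nodeNet, protein = nodeProt,
                          description = desc, go = go,
                          stringsAsFactors = FALSE)

    intra <- do.call(rbind, lapply(seq_len(N), function(i) {
        g <- interactionGraph(nets[[i]])
        sg <- igraph::induced_subgraph(g, alignment@rows[, i])
        if (igraph::ecount(sg) == 0)
            return(NULL)
        e <- igraph::as_data_frame(sg, what = "edges")
        data.frame(from = paste0(alignment@networks[i], "::", e$from),
                   to = paste0(alignment@networks[i], "::", e$to),
                   network = alignment@networks[i], weight = e$weight,
                   color = .weightColor(e$weight), style = "solid",
                   stringsAsFactors = FALSE)
    }))
    if (is.null(intra))
        intra <- data.frame(from = character(), to = character(),
                            network = character(), weight = numeric(),
                            color = character(), style = character(),
                            stringsAsFactors = FALSE)

    pairIdx <- if (N >= 2) utils::combn(N, 2) else matrix(integer(), 2, 0)
    inter <- do.call(rbind, lapply(seq_len(k), function(r) {
        data.frame(
            from = paste0(alignment@networks[pairIdx[1, ]], "::",
                          alignment@rows[r, pairIdx[1, ]]),
            to = paste0(alignment@networks[pairIdx[2, ]], "::",
                        alignment@rows[r, pairIdx[2, ]]),
            network1 = alignment@networks[pairIdx[1, ]],
            network2 = alignment@networks[pairIdx[2, ]],
            row = r, style = "dashed", stringsAsFactors = FALSE)
    }))
    new("AlignmentGraph", nodes = nodesDf, intraEdges = intra,
        interEdges = inter)
}

#' Export an alignment graph as GraphML
#'
#' Writes the merged alignment graph in GraphML with node attributes
#' `network`, `protein`, `description`, `go` and edge attributes `kind`
#' (`intra`/`inter`), `weight`, `color` and `style`, ready for any
#' GraphML-aware viewer or layout engine.
#'
#' @param graph an [AlignmentGraph-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGraphML <- function(graph, path) {
    doc <- xml2::xml_new_root("graphml",
        xmlns = "http://graphml.graphdrawing.org/xmlns")
    keys <- list(
        c("d_network", "node", "network", "string"),
        c("d_protein", "node", "protein", "string"),
        c("d_description", "node", "description", "string"),
        c("d_go", "node", "go", "string"),
        c("d_kind", "edge", "kind", "string"),
        c("d_weight", "edge", "weight", "double"),
        c("d_color", "edge", "color", "string"),
        c("d_style", "edge", "style", "string"))
    for (kk in keys)
        xml2::xml_add_child(doc, "key", id = kk[1], "for" = kk[2],
                            attr.name = kk[3], attr.type = kk[4])
    g <- xml2::xml_add_child(doc, "graph", id = "alignment",
                             edgedefault = "undirected")
    addData <- function(node, key, value) {
        d <- xml2::xml_add_child(node, "data", key = key)
        xml2::xml_set_text(d, as.character(value))
    }
    nd <- graph@nodes
    for (i in seq_len(nrow(nd))) {
        n <- xml2::xml_add_child(g, "node", id = nd$id[i])
        addData(n, "d_network", nd$network[i])
        addData(n, "d_protein", nd$protein[i])
        addData(n, "d_description",
                if (is.na(nd$description[i])) "" else nd$description[i])
        addData(n, "d_go", nd$go[i])
    }
    ia <- graph@intraEdges
    for (i in seq_len(nrow(ia))) {
        e <- xml2::xml_add_child(g, "edge", source = ia$from[i],
                                 target = ia$to[i])
        addData(e, "d_kind", "intra")
        addData(e, "d_weight", sprintf("%.6f", ia$weight[i]))
        addData(e, "d_color", ia$color[i])
        addData(e, "d_style", "solid")
    }
    ie <- graph@interEdges
    for (i in seq_len(nrow(ie))) {
        e <- xml2::xml_add_child(g, "edge", source = ie$from[i],
                                 target = ie$to[i])
        addData(e, "d_kind", "inter")
        addData(e, "d_style", "dashed")
    }
    xml2::write_xml(doc, path)
    invisible(path)
}
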