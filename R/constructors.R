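#' @include AllGenerics.R
NULL

#' Construct a PPINetwork from an edge table
#'
#' Programmatic constructor used by the file reader and the synthetic
#' generator.  Self-loops are dropped (their endpoint is retained as an
#' isolated node) and duplicate edges are collapsed to their maximum
#' weight, so the class invariants hold by construction.
#'
#' @param networkId single character label.
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `weight` (defaulting to 1); weights must already be in `[0, 1]`.
#' @param nodes optional character vector of additional node names (e.g.
#'   isolated vertices that appear in no edge).
#' @return a [PPINetwork-class] object.
#' @examples
#' net <- PPINetwork("sc", data.frame(from = "P1", to = "P2", weight = 0.8))
#' nodes(net)
#' @export
PPINetwork <- function(networkId, edges, nodes = NULL) {
    if (is.null(edges$weight)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to   <- as.character(edges$to)
    loop <- edges$from == edges$to
    loopNodes <- unique(edges$from[loop])
    edges <- edges[!loop, , drop = FALSE]
    if (nrow(edges) > 0) {
        a <- pmin(edges$from, edges$to)
        b <- pmax(edges$from, edges$to)
        key <- paste(a, b, sep = "\r")
        w <- vapply(split(edges$weight, key), max, numeric(1))
        uk <- unique(key)                        # first-appearance order
        ab <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
        edges <- data.frame(from = ab[, 1], to = ab[, 2],
                            weight = as.numeric(w[uk]),
                            stringsAsFactors = FALSE)
    }
    allNodes <- unique(c(edges$from, edges$to, loopNodes, nodes))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = allNodes)
    new("PPINetwork", networkId = as.character(networkId), graph = g)
}

#' Construct a bit-score SimilarityStore
#'
#' @param pairs data.frame with columns `p1`, `p2`, `score`.  Pairs are
#'   symmetric; duplicates keep the maximum score.
#' @return a [SimilarityStore-class] in `"bitscore"` mode.
#' @export
bitScoreStore <- function(pairs = data.frame(p1 = character(),
                                             p2 = character(),
                                             score = numeric())) {
    p1 <- as.character(pairs$p1)
    p2 <- as.character(pairs$p2)
    sc <- as.numeric(pairs$score)
    a <- pmin(p1, p2); b <- pmax(p1, p2)
    key <- paste(a, b, sep = "\r")
    if (anyDuplicated(key)) {
        sc <- vapply(split(sc, key), max, numeric(1))
        uk <- unique(key)
        sc <- as.numeric(sc[uk])
        ab <- do.call(rbind, strsplit(uk, "\r", fixed = TRUE))
        a <- ab[, 1]; b <- ab[, 2]
    }
    new("SimilarityStore", mode = "bitscore",
        pairs = data.frame(p1 = a, p2 = b, score = sc,
                           stringsAsFactors = FALSE),
        groups = list())
}

#' Construct an orthology-group SimilarityStore
#'
#' @param membership named list: protein id -> character vector of
#'   orthology-group ids (COG/KOG/NOG or similar opaque labels).
#' @return a [SimilarityStore-class] in `"cog"` mode; the implied score of
#'   a protein pair is the number of shared groups.
#' @export
cogStore <- function(membership = list()) {
    membership <- lapply(membership, function(g) unique(as.character(g)))
    new("SimilarityStore", mode = "cog",
        pairs = data.frame(p1 = character(), p2 = character(),
                           score = numeric(), stringsAsFactors = FALSE),
        groups = membership)
}

#' Construct an AnnotationStore
#'
#' @param descriptions named character vector, protein -> description.
#' @param terms named list, protein -> list(cc, bp, mf, unclassified).
#' @return an [AnnotationStore-class] object.
#' @export
annotationStore <- function(descriptions = character(), terms = list()) {
    new("AnnotationStore", descriptions = descriptions, terms = terms)
}

#' Construct an Alignment
#'
#' @param networks character vector of network ids (column order).
#' @param rows character matrix of aligned protein ids, one column per
#'   network.
#' @param metadata optional list of auxiliary values.
#' @return an [Alignment-class] object.
#' @examples
#' Alignment(c("a", "b"), rbind(c("p1", "q1"), c("p2", "q2")))
#' @export
Alignment <- function(networks, rows, metadata = list()) {
    rows <- as.matrix(rows)
    storage.mode(rows) <- "character"
    colnames(rows) <- networks
    new("Alignment", networks = as.character(networks), rows = rows,
        metadata = metadata)
}

#' Aligner configuration
#'
#' Bundles the six user-facing parameters of the aligner with the RNG seed
#' and the restart count.  The defaults are the recommended values for
#' real PPI networks; for very sparse networks a `sigma` of 1 or 2 is
#' recommended instead of 7.
#'
#' @param iterSeed Gibbs iterations in the bootstrap (seed) phase.
#' @param iterExtend Gibbs iterations per extension step.
#' @param sigma minimum degree of candidate seed nodes.
#' @param overlap maximum allowed fraction of common nodes between two
#'   distinct alignments.
#' @param refine number of refinement iterations.
#' @param minComplexSize minimum rows of a reported conserved complex.
#' @param seed integer RNG seed.
#' @param restarts independent seed attempts; `NA` (default) means one per
#'   candidate seed node of the smallest network, capped at 100.
#' @return an [AlignmentConfig-class] object.
#' @examples
#' alignmentConfig(sigma = 2, seed = 7)
#' @export
alignmentConfig <- function(iterSeed = 200L, iterExtend = 200L, sigma = 7L,
                            overlap = 0.5, refine = 10L, minComplexSize = 5L,
                            seed = 1L, restarts = NA_integer_) {
    new("AlignmentConfig",
        iterSeed = as.integer(iterSeed), iterExtend = as.integer(iterExtend),
        sigma = as.integer(sigma), overlap = as.numeric(overlap),
        refine = as.integer(refine),
        minComplexSize = as.integer(minComplexSize),
        seed = as.integer(seed), restarts = as.integer(restarts))
}
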