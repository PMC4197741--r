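#' @include ppiAlign-package.R
NULL

#' PPINetwork: one species' protein-protein interaction network
#'
#' An undirected, weighted interaction graph for a single species (or other
#' network source).  Edge weights are interaction probabilities in `[0, 1]`,
#' as in STRING-style combined scores after rescaling.  Self-loops are never
#' stored; duplicate edges are collapsed to the maximum weight.
#'
#' @slot networkId single character label, unique within a run.
#' @slot graph an undirected [igraph::igraph] with named vertices and a
#'   numeric `weight` edge attribute.
#'
#' @seealso [readPPINetwork()], [PPINetwork()]
#' @export
setClass("PPINetwork", slots = c(networkId = "character", graph = "ANY"))

setValidity("PPINetwork", function(object) {
    msg <- character()
    if (length(object@networkId) != 1L || is.na(object@networkId) ||
        !nzchar(object@networkId))
        msg <- c(msg, "'networkId' must be a single non-empty string")
    g <- object@graph
    if (!inherits(g, "igraph")) {
        msg <- c(msg, "'graph' must be an igraph object")
    } else {
        if (igraph::is_directed(g))
            msg <- c(msg, "interaction graph must be undirected")
        if (igraph::ecount(g) > 0 && any(igraph::which_loop(g)))
            msg <- c(msg, "interaction graph must not contain self-loops")
        nm <- igraph::V(g)$name
        if (is.null(nm) || anyNA(nm) || !all(nzchar(nm)))
            msg <- c(msg, "all vertices must carry non-empty names")
        else if (anyDuplicated(nm))
            msg <- c(msg, "vertex names must be unique")
        if (igraph::ecount(g) > 0) {
            w <- igraph::E(g)$weight
            if (is.null(w) || anyNA(w) || any(w < 0) || any(w > 1))
                msg <- c(msg,
                    "edge weights must be interaction probabilities in [0, 1]")
        }
    }
    if (length(msg)) msg else TRUE
})

#' SimilarityStore: cross-network protein similarity
#'
#' Holds orthology similarity in one of two dialects: `"bitscore"` (pairwise
#' BLAST bit scores between proteins of different networks) or `"cog"`
#' (orthology-group membership; the implied score of a protein pair is the
#' number of shared groups).
#'
#' @slot mode `"bitscore"` or `"cog"`.
#' @slot pairs data.frame with columns `p1`, `p2`, `score` (bitscore mode;
#'   pairs are stored once with `p1 <= p2` lexicographically).
#' @slot groups named list mapping protein id to a character vector of
#'   orthology-group ids (cog mode).
#'
#' @seealso [readBitScores()], [readCogGroups()], [pairScore()]
#' @export
setClass("SimilarityStore",
    slots = c(mode = "character", pairs = "data.frame", groups = "list"))

setValidity("SimilarityStore", function(object) {
    msg <- character()
    if (length(object@mode) != 1L || !object@mode %in% c("bitscore", "cog"))
        msg <- c(msg, "'mode' must be \"bitscore\" or \"cog\"")
    p <- object@pairs
    if (!all(c("p1", "p2", "score") %in% names(p)))
        msg <- c(msg, "'pairs' needs columns p1, p2, score")
    else {
        if (nrow(p) > 0) {
            if (any(!is.finite(p$score)) || any(p$score < 0))
                msg <- c(msg, "scores must be non-negative finite numbers")
            if (any(p$p1 > p$p2))
                msg <- c(msg, "pairs must be stored with p1 <= p2")
            if (anyDuplicated(paste(p$p1, p$p2, sep = "\r")))
                msg <- c(msg, "duplicate protein pairs in store")
        }
    }
    if (length(object@groups) > 0 &&
        (is.null(names(object@groups)) || any(!nzchar(names(object@groups)))))
        msg <- c(msg, "'groups' must be a named list")
    if (length(msg)) msg else TRUE
})

#' AnnotationStore: protein descriptions and GO terms
#'
#' Purely decorative annotation attached to alignment-graph nodes for
#' interpretation.  Annotations are never consulted when computing
#' alignments, so their presence or absence cannot change any result.
#'
#' @slot descriptions named character vector, protein id -> description.
#' @slot terms named list, protein id -> list with character-vector elements
#'   `cc`, `bp`, `mf`, `unclassified` (cellular component, biological
#'   process, molecular function, unrouted).
#'
#' @seealso [readAnnotations()]
#' @export
setClass("AnnotationStore",
    slots = c(descriptions = "character", terms = "list"))

setValidity("AnnotationStore", function(object) {
    msg <- character()
    if (length(object@descriptions) > 0 && is.null(names(object@descriptions)))
        msg <- c(msg, "'descriptions' must be named by protein id")
    if (length(object@terms) > 0) {
        if (is.null(names(object@terms)))
            msg <- c(msg, "'terms' must be named by protein id")
        ok <- vapply(object@terms, function(t)
            is.list(t) && all(c("cc", "bp", "mf", "unclassified") %in% names(t)),
            logical(1))
        if (!all(ok))
            msg <- c(msg, "each terms entry needs cc/bp/mf/unclassified slots")
    }
    if (length(msg)) msg else TRUE
})

#' Alignment: a multiple local alignment of N networks
#'
#' An ordered set of rows, each row one protein per network (a putative
#' functional-orthology tuple).  Within each network's column all proteins
#' are distinct: the alignment is a one-to-one mapping between the aligned
#' subgraphs.
#'
#' @slot networks character vector of network ids, fixing the column order.
#' @slot rows character matrix, one row per aligned tuple, one column per
#'   network (colnames are the network ids).
#' @slot metadata free-form list (density/ISC summaries, phase traces).
#'
#' @seealso [alignNetworks()], [localDensity()], [iscScore()]
#' @export
setClass("Alignment",
    slots = c(networks = "character", rows = "matrix", metadata = "list"))

setValidity("Alignment", function(object) {
    msg <- character()
    nets <- object@networks
    if (length(nets) < 2L || anyNA(nets) || anyDuplicated(nets))
        msg <- c(msg, "'networks' must be >= 2 unique network ids")
    r <- object@rows
    if (!is.character(r))
        msg <- c(msg, "'rows' must be a character matrix")
    else {
        if (ncol(r) != length(nets))
            msg <- c(msg, "one column per network required")
        if (nrow(r) < 1L)
            msg <- c(msg, "an alignment needs at least one row")
        if (anyNA(r) || any(!nzchar(r)))
            msg <- c(msg, "row members must be non-empty protein ids")
        else if (any(apply(r, 2, anyDuplicated) > 0))
            msg <- c(msg,
                "column-wise injectivity violated: duplicate protein within a network column")
    }
    if (length(msg)) msg else TRUE
})

#' AlignmentConfig: tuning parameters of the aligner
#'
#' The six user-facing parameters plus the RNG seed and the number of
#' independent restarts.
#'
#' @slot iterSeed Gibbs iterations in the bootstrap (seed) phase.
#' @slot iterExtend Gibbs iterations per extension step.
#' @slot sigma minimum network degree of seed candidates.
#' @slot overlap maximum allowed fraction of common nodes between two
#'   alignments that are still considered distinct, in `[0, 1]`.
#' @slot refine number of refinement iterations.
#' @slot minComplexSize minimum number of rows of a reported alignment.
#' @slot seed integer RNG seed; identical seed + inputs give identical output.
#' @slot restarts number of independent seed attempts; `NA` means "one per
#'   candidate seed node of the smallest network, capped at 100".
#'
#' @seealso [alignmentConfig()]
#' @export
setClass("AlignmentConfig",
    slots = c(iterSeed = "integer", iterExtend = "integer", sigma = "integer",
              overlap = "numeric", refine = "integer",
              minComplexSize = "integer", seed = "integer",
              restarts = "integer"))

setValidity("AlignmentConfig", function(object) {
    msg <- character()
    one <- function(x) length(x) == 1L
    if (!one(object@iterSeed) || is.na(object@iterSeed) || object@iterSeed < 0L)
        msg <- c(msg, "'iterSeed' must be a non-negative integer")
    if (!one(object@iterExtend) || is.na(object@iterExtend) ||
        object@iterExtend < 0L)
        msg <- c(msg, "'iterExtend' must be a non-negative integer")
    if (!one(object@sigma) || is.na(object@sigma) || object@sigma < 0L)
        msg <- c(msg, "'sigma' must be a non-negative integer")
    if (!one(object@overlap) || is.na(object@overlap) ||
        object@overlap < 0 || object@overlap > 1)
        msg <- c(msg, "'overlap' must lie in [0, 1]")
    if (!one(object@refine) || is.na(object@refine) || object@refine < 0L)
        msg <- c(msg, "'refine' must be a non-negative integer")
    if (!one(object@minComplexSize) || is.na(object@minComplexSize) ||
        object@minComplexSize < 1L)
        msg <- c(msg, "'minComplexSize' must be >= 1")
    if (!one(object@seed) || is.na(object@seed))
        msg <- c(msg, "'seed' must be a single integer")
    if (!one(object@restarts) ||
        (!is.na(object@restarts) && object@restarts < 1L))
        msg <- c(msg, "'restarts' must be NA or >= 1")
    if (length(msg)) msg else TRUE
})

#' AlignmentGraph: merged visualization model of one alignment
#'
#' The exportable graph joining the aligned subgraphs of all networks:
#' intra-edges are the within-network interactions of the induced subgraphs
#' (solid, colour-classed green/yellow/red by weight band) and inter-edges
#' are the cross-network links of each alignment row (dashed).
#'
#' @slot nodes data.frame: `id`, `network`, `protein`, `description`, `go`.
#' @slot intraEdges data.frame: `from`, `to`, `network`, `weight`, `color`,
#'   `style` (always `"solid"`).
#' @slot interEdges data.frame: `from`, `to`, `network1`, `network2`, `row`,
#'   `style` (always `"dashed"`).
#'
#' @seealso [buildAlignmentGraph()], [writeGraphML()]
#' @export
setClass("AlignmentGraph",
    slots = c(nodes = "data.frame", intraEdges = "data.frame",
              interEdges = "data.frame"))

setValidity("AlignmentGraph", function(object) {
    msg <- character()
    if (!all(c("id", "network", "protein") %in% names(object@nodes)))
        msg <- c(msg, "'nodes' needs id/network/protein columns")
    ia <- object@intraEdges
    if (!all(c("from", "to", "network", "weight", "color") %in% names(ia)))
        msg <- c(msg, "'intraEdges' needs from/to/network/weight/color")
    ie <- object@interEdges
    if (!all(c("from", "to", "network1", "network2", "row") %in% names(ie)))
        msg <- c(msg, "'interEdges' needs from/to/network1/network2/row")
    else if (nrow(ie) > 0 && any(ie$network1 == ie$network2))
        msg <- c(msg, "inter-edges must join two different networks")
    if (length(msg)) msg else TRUE
})

#' FixtureSpec: recipe for a synthetic alignment benchmark
#'
#' Describes a family of random networks with planted conserved complexes:
#' Erdos-Renyi background graphs, per-complex counterpart nodes wired
#' densely with high weights in every network, counterpart bit scores far
#' above random decoy scores.  Plantings are detectable by construction
#' (`q > backgroundEdgeProb`, `plantedSim > max(decoySimRange)`).
#'
#' @slot nNetworks number of networks (>= 2).
#' @slot backgroundNodes nodes per network.
#' @slot backgroundEdgeProb Erdos-Renyi edge probability of the background.
#' @slot complexes list of plantings, each a list with `size`, `q`
#'   (intra-complex edge probability), `wMin`, `wMax` (intra-complex weight
#'   range).
#' @slot plantedSim bit score assigned to counterpart pairs.
#' @slot decoySimRange length-2 numeric, score range of random decoy pairs.
#' @slot decoysPerPair number of decoy pairs per network pair.
#' @slot seed integer RNG seed of the generator.
#'
#' @seealso [fixtureSpec()], [generateFixture()]
#' @export
setClass("FixtureSpec",
    slots = c(nNetworks = "integer", backgroundNodes = "integer",
              backgroundEdgeProb = "numeric", complexes = "list",
              plantedSim = "numeric", decoySimRange = "numeric",
              decoysPerPair = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    msg <- character()
    if (object@nNetworks < 2L)
        msg <- c(msg, "at least two networks are required")
    if (object@backgroundNodes < 1L)
        msg <- c(msg, "'backgroundNodes' must be positive")
    if (object@backgroundEdgeProb < 0 || object@backgroundEdgeProb > 1)
        msg <- c(msg, "'backgroundEdgeProb' must lie in [0, 1]")
    for (cx in object@complexes) {
        if (!all(c("size", "q", "wMin", "wMax") %in% names(cx))) {
            msg <- c(msg, "each complex needs size/q/wMin/wMax")
            next
        }
        if (cx$q <= object@backgroundEdgeProb)
            msg <- c(msg,
                "planted edge probability q must exceed backgroundEdgeProb")
        if (cx$wMin > cx$wMax || cx$wMin < 0 || cx$wMax > 1)
            msg <- c(msg, "complex weight range must satisfy 0 <= wMin <= wMax <= 1")
        if (cx$size < 1L)
            msg <- c(msg, "complex size must be positive")
    }
    total <- sum(vapply(object@complexes, function(cx) as.integer(cx$size), 1L))
    if (length(object@complexes) && total > object@backgroundNodes)
        msg <- c(msg, "planted complexes do not fit into 'backgroundNodes'")
    if (length(object@decoySimRange) != 2L ||
        any(object@decoySimRange < 0) || diff(object@decoySimRange) < 0)
        msg <- c(msg, "'decoySimRange' must be an increasing non-negative pair")
    if (length(object@complexes) &&
        object@plantedSim <= max(object@decoySimRange))
        msg <- c(msg, "'plantedSim' must exceed the maximum decoy similarity")
    if (object@decoysPerPair < 0L)
        msg <- c(msg, "'decoysPerPair' must be non-negative")
    if (length(msg)) msg else TRUE
})
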