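#' @include AllGenerics.R constructors.R
NULL

#' @describeIn PPINetwork-class the network's label.
#' @param x a `PPINetwork`.
#' @export
setMethod("networkId", "PPINetwork", function(x) x@networkId)

#' @describeIn PPINetwork-class protein ids (vertex names).
#' @export
setMethod("nodes", "PPINetwork", function(x, ...) igraph::V(x@graph)$name)

#' @describeIn PPINetwork-class the underlying undirected igraph.
#' @export
setMethod("interactionGraph", "PPINetwork", function(x) x@graph)

#' @describeIn PPINetwork-class the weighted edge table
#'   (`from`/`to`/`weight`).
#' @export
setMethod("interactions", "PPINetwork", function(x) {
    if (igraph::ecount(x@graph) == 0)
        return(data.frame(from = character(), to = character(),
                          weight = numeric(), stringsAsFactors = FALSE))
    e <- igraph::as_data_frame(x@graph, what = "edges")
    data.frame(from = e$from, to = e$to, weight = e$weight,
               stringsAsFactors = FALSE)
})

setMethod("show", "PPINetwork", function(object) {
    cat(sprintf("PPINetwork '%s': %d proteins, %d weighted interactions\n",
                object@networkId, igraph::vcount(object@graph),
                igraph::ecount(object@graph)))
})

#' @describeIn SimilarityStore-class `"bitscore"` or `"cog"`.
#' @param x a `SimilarityStore`.
#' @export
setMethod("similarityMode", "SimilarityStore", function(x) x@mode)

#' @describeIn SimilarityStore-class similarity score of a protein pair:
#'   the stored bit score, or the number of shared orthology groups in cog
#'   mode; 0 for unlisted pairs.
#' @param a,b protein identifiers.
#' @export
setMethod("pairScore", "SimilarityStore", function(x, a, b) {
    a <- as.character(a); b <- as.character(b)
    if (x@mode == "cog") {
        ga <- x@groups[[a]]; gb <- x@groups[[b]]
        if (is.null(ga) || is.null(gb)) return(0)
        return(length(intersect(ga, gb)))
    }
    key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
    i <- match(key, paste(x@pairs$p1, x@pairs$p2, sep = "\r"))
    if (is.na(i)) 0 else x@pairs$score[i]
})

setMethod("show", "SimilarityStore", function(object) {
    if (object@mode == "bitscore")
        cat(sprintf("SimilarityStore (bitscore): %d protein pairs\n",
                    nrow(object@pairs)))
    else
        cat(sprintf("SimilarityStore (cog): %d proteins, %d orthology groups\n",
                    length(object@groups),
                    length(unique(unlist(object@groups)))))
})

#' @describeIn AnnotationStore-class named description vector.
#' @param x an `AnnotationStore`.
#' @export
setMethod("descriptions", "AnnotationStore", function(x) x@descriptions)

#' @describeIn AnnotationStore-class GO terms of one protein as a list with
#'   `cc`, `bp`, `mf` and `unclassified` character vectors (all empty when
#'   the protein is unannotated).
#' @param protein a protein identifier.
#' @export
setMethod("goTerms", "AnnotationStore", function(x, protein) {
    t <- x@terms[[as.character(protein)]]
    if (is.null(t))
        t <- list(cc = character(), bp = character(), mf = character(),
                  unclassified = character())
    t
})

setMethod("show", "AnnotationStore", function(object) {
    cat(sprintf("AnnotationStore: %d described, %d GO-annotated proteins\n",
                length(object@descriptions), length(object@terms)))
})

#' @describeIn Alignment-class the row matrix (one protein per network per
#'   row).
#' @param x an `Alignment`.
#' @export
setMethod("alignmentRows", "Alignment", function(x) x@rows)

#' @describeIn Alignment-class the aligned network ids, in column order.
#' @export
setMethod("alignedNetworks", "Alignment", function(x) x@networks)

#' @describeIn Alignment-class number of rows (the size of the conserved
#'   complex).
#' @export
setMethod("alignmentSize", "Alignment", function(x) nrow(x@rows))

setMethod("show", "Alignment", function(object) {
    cat(sprintf("Alignment of %d networks (%s): %d rows\n",
                length(object@networks),
                paste(object@networks, collapse = ", "),
                nrow(object@rows)))
    if (!is.null(object@metadata$density))
        cat(sprintf("  density %.4f", object@metadata$density))
    if (!is.null(object@metadata$isc))
        cat(sprintf("  ISC %.2f%%", object@metadata$isc))
    if (!is.null(object@metadata$density) || !is.null(object@metadata$isc))
        cat("\n")
    n <- min(3L, nrow(object@rows))
    for (i in seq_len(n))
        cat("  ", paste(object@rows[i, ], collapse = " <-> "), "\n", sep = "")
    if (nrow(object@rows) > n) cat("  ...\n")
})

setMethod("show", "AlignmentConfig", function(object) {
    cat("AlignmentConfig:\n")
    cat(sprintf("  iterSeed=%d iterExtend=%d sigma=%d\n",
                object@iterSeed, object@iterExtend, object@sigma))
    cat(sprintf("  overlap=%g refine=%d minComplexSize=%d\n",
                object@overlap, object@refine, object@minComplexSize))
    cat(sprintf("  seed=%d restarts=%s\n", object@seed,
                ifelse(is.na(object@restarts), "auto",
                       as.character(object@restarts))))
})

setMethod("show", "AlignmentGraph", function(object) {
    cat(sprintf("AlignmentGraph: %d nodes, %d intra-edges, %d inter-edges\n",
                nrow(object@nodes), nrow(object@intraEdges),
                nrow(object@interEdges)))
})

setMethod("show", "FixtureSpec", function(object) {
    cat(sprintf(
        "FixtureSpec: %d networks x %d nodes (p=%.3g), %d planted complex(es), seed %d\n",
        object@nNetworks, object@backgroundNodes, object@backgroundEdgeProb,
        length(object@complexes), object@seed))
})
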