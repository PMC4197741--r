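#' @include io-network.R
NULL

#' Read cross-network BLAST bit scores
#'
#' Each data line holds two protein ids of *different* networks and their
#' BLAST bit score.  Pairs whose two proteins can only be placed within
#' one and the same network are an error; pairs referencing proteins that
#' occur in none of the loaded networks are skipped with a warning.
#'
#' @param path path to the three-column bit-score file.
#' @param networks list of [PPINetwork-class] objects the scores refer to.
#' @return a [SimilarityStore-class] in `"bitscore"` mode.
#' @export
readBitScores <- function(path, networks) {
    nodesPerNet <- lapply(networks, nodes)
    lines <- .readDataLines(path)
    if (length(lines) == 0) return(bitScoreStore())
    parts <- .splitFields(lines)
    if (any(lengths(parts) != 3L))
        stop(sprintf("%s: line '%s' does not have exactly three fields",
                     path, lines[which(lengths(parts) != 3L)[1]]),
             call. = FALSE)
    p1 <- vapply(parts, `[`, character(1), 1L)
    p2 <- vapply(parts, `[`, character(1), 2L)
    sc <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3L)))
    if (anyNA(sc) || any(!is.finite(sc)))
        stop(sprintf("%s: non-numeric bit score in line '%s'",
                     path, lines[which(!is.finite(sc))[1]]), call. = FALSE)
    if (any(sc < 0))
        stop(sprintf("%s: negative bit score in line '%s'",
                     path, lines[which(sc < 0)[1]]), call. = FALSE)
    m1 <- vapply(nodesPerNet, function(nn) p1 %in% nn,
                 logical(length(p1)))
    m2 <- vapply(nodesPerNet, function(nn) p2 %in% nn,
                 logical(length(p2)))
    if (length(p1) == 1L) { m1 <- rbind(m1); m2 <- rbind(m2) }
    known1 <- rowSums(m1) > 0
    known2 <- rowSums(m2) > 0
    # cross-network placement exists: p1 in net i, p2 in net j, i != j
    cross <- vapply(seq_along(p1), function(r) {
        any(outer(m1[r, ], m2[r, ], function(i, j) i & j) &
            !diag(length(networks)))
    }, logical(1))
    unknown <- !known1 | !known2
    if (any(known1 & known2 & !cross))
        stop(sprintf(
            "%s: pair '%s %s' joins proteins of one single network",
            path, p1[which(known1 & known2 & !cross)[1]],
            p2[which(known1 & known2 & !cross)[1]]), call. = FALSE)
    if (any(unknown))
        warning(sprintf(
            "%s: skipped %d pair(s) referencing proteins absent from every network",
            path, sum(unknown)), call. = FALSE)
    keep <- !unknown
    bitScoreStore(data.frame(p1 = p1[keep], p2 = p2[keep], score = sc[keep],
                             stringsAsFactors = FALSE))
}

#' Read orthology-group (COG/KOG/NOG) membership
#'
#' Each data line is a protein id followed by one or more orthology-group
#' identifiers.  Multiple lines for one protein are merged.  The implied
#' similarity of a protein pair is the number of shared groups.
#'
#' @param path path to the membership file.
#' @return a [SimilarityStore-class] in `"cog"` mode.
#' @export
readCogGroups <- function(path) {
    lines <- .readDataLines(path)
    if (length(lines) == 0) return(cogStore())
    parts <- .splitFields(lines)
    if (any(lengths(parts) < 2L))
        stop(sprintf("%s: line '%s' lists no orthology groups",
                     path, lines[which(lengths(parts) < 2L)[1]]),
             call. = FALSE)
    prot <- vapply(parts, `[`, character(1), 1L)
    grps <- lapply(parts, `[`, -1L)
    membership <- tapply(grps, prot, function(g) unique(unlist(g)),
                         simplify = FALSE)
    cogStore(as.list(membership))
}

#' Write a bit-score similarity file
#'
#' @param sim a [SimilarityStore-class] in bitscore mode.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeBitScores <- function(sim, path) {
    stopifnot(similarityMode(sim) == "bitscore")
    p <- sim@pairs
    writeLines(sprintf("%s\t%s\t%g", p$p1, p$p2, p$score), path)
    invisible(path)
}

#' Write an orthology-group membership file
#'
#' @param sim a [SimilarityStore-class] in cog mode.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCogGroups <- function(sim, path) {
    stopifnot(similarityMode(sim) == "cog")
    writeLines(vapply(names(sim@groups), function(p)
        paste(c(p, sim@groups[[p]]), collapse = "\t"), character(1)), path)
    invisible(path)
}
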