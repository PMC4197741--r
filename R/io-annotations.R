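#' @include io-similarity.R
NULL

# Minimal namespace lookup for frequent GO terms, used when a term id
# carries no C:/P:/F: namespace prefix.  Unknown ids fall into the
# "unclassified" bucket; routing is decorative and never affects results.
.GO_NAMESPACE <- c(
    "GO:0005737" = "cc", "GO:0005634" = "cc", "GO:0005739" = "cc",
    "GO:0005886" = "cc", "GO:0005829" = "cc", "GO:0005783" = "cc",
    "GO:0005794" = "cc", "GO:0005730" = "cc", "GO:0005576" = "cc",
    "GO:0016020" = "cc", "GO:0005840" = "cc", "GO:0005681" = "cc",
    "GO:0006412" = "bp", "GO:0006355" = "bp", "GO:0008152" = "bp",
    "GO:0006281" = "bp", "GO:0007049" = "bp", "GO:0006468" = "bp",
    "GO:0055085" = "bp", "GO:0006508" = "bp", "GO:0016192" = "bp",
    "GO:0006914" = "bp", "GO:0006351" = "bp", "GO:0008380" = "bp",
    "GO:0003677" = "mf", "GO:0003723" = "mf", "GO:0005524" = "mf",
    "GO:0016740" = "mf", "GO:0016787" = "mf", "GO:0004672" = "mf",
    "GO:0005198" = "mf", "GO:0003824" = "mf", "GO:0046872" = "mf",
    "GO:0005515" = "mf")

.isGoTerm <- function(x) grepl("^((C|P|F|CC|BP|MF):)?GO:[0-9]+$", x)

.routeGoTerm <- function(term) {
    if (grepl("^(C|CC):", term)) return("cc")
    if (grepl("^(P|BP):", term)) return("bp")
    if (grepl("^(F|MF):", term)) return("mf")
    ns <- .GO_NAMESPACE[term]
    if (is.na(ns)) "unclassified" else unname(ns)
}

.stripGoPrefix <- function(term) sub("^(C|P|F|CC|BP|MF):", "", term)

#' Read a GO annotation file
#'
#' Each data line is a protein id, an optional free-text description, and
#' zero or more GO term identifiers (optionally prefixed `C:`/`P:`/`F:` to
#' name their namespace).  Terms without a prefix are routed through a
#' small built-in namespace table; unknown terms land in an
#' "unclassified" bucket.  The file is lenient: proteins absent from the
#' loaded networks are retained.  Annotations are decorative only and
#' never change an alignment.
#'
#' @param path path to the annotation file.
#' @return an [AnnotationStore-class].
#' @export
readAnnotations <- function(path) {
    lines <- .readDataLines(path)
    if (length(lines) == 0) return(annotationStore())
    parts <- .splitFields(lines)
    desc <- character()
    terms <- list()
    emptyTerms <- list(cc = character(), bp = character(), mf = character(),
                       unclassified = character())
    for (p in parts) {
        prot <- p[1L]
        rest <- p[-1L]
        isTerm <- .isGoTerm(rest)
        d <- paste(rest[!isTerm], collapse = " ")
        if (nzchar(d) && is.na(desc[prot])) desc[prot] <- d
        t <- terms[[prot]]
        if (is.null(t)) t <- emptyTerms
        for (term in rest[isTerm]) {
            ns <- .routeGoTerm(term)
            t[[ns]] <- unique(c(t[[ns]], .stripGoPrefix(term)))
        }
        terms[[prot]] <- t
    }
    annotationStore(descriptions = desc[!is.na(desc)], terms = terms)
}

#' Write a GO annotation file
#'
#' @param annotations an [AnnotationStore-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeAnnotations <- function(annotations, path) {
    prots <- union(names(annotations@descriptions), names(annotations@terms))
    lines <- vapply(prots, function(p) {
        d <- annotations@descriptions[p]
        t <- goTerms(annotations, p)
        tagged <- c(if (length(t$cc)) paste0("C:", t$cc),
                    if (length(t$bp)) paste0("P:", t$bp),
                    if (length(t$mf)) paste0("F:", t$mf),
                    t$unclassified)
        paste(c(p, if (!is.na(d)) gsub("[ \t]+", "_", d), tagged),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
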