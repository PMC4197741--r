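#' @include constructors.R
NULL

# Read non-blank, non-comment ('#'-prefixed) lines of a text input file.
.readDataLines <- function(path) {
    if (length(path) != 1L || !file.exists(path))
        stop("cannot read file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines[nzchar(lines) & !startsWith(lines, "#")]
}

.splitFields <- function(lines) strsplit(lines, "[ \t]+")

#' Read a PPI network from a weighted edge-list file
#'
#' Networks are plain text, one interaction per line: two protein ids
#' separated by spaces or tabs, optionally followed by a weight.  Lines
#' starting with `#` and blank lines are ignored.  A missing weight
#' defaults to 1.  Weights must be interaction probabilities in `[0, 1]`;
#' values in `(1, 1000]` are interpreted as STRING-style combined scores
#' and divided by 1000.  Self-loops are dropped (the node is kept) and
#' duplicate edges keep their maximum weight.
#'
#' @param path path to the edge-list file.
#' @param networkId label for the network; defaults to the file base name.
#' @return a [PPINetwork-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("P1\tP2\t0.8", "A B 700"), f)
#' net <- readPPINetwork(f, "demo")
#' interactions(net)
#' @export
readPPINetwork <- function(path,
                           networkId = tools::file_path_sans_ext(basename(path))) {
    lines <- .readDataLines(path)
    if (length(lines) == 0)
        return(PPINetwork(networkId,
                          data.frame(from = character(), to = character(),
                                     weight = numeric())))
    parts <- .splitFields(lines)
    nf <- lengths(parts)
    if (any(nf < 2L))
        stop(sprintf("%s: line '%s' has fewer than two fields",
                     path, lines[which(nf < 2L)[1]]), call. = FALSE)
    from <- vapply(parts, `[`, character(1), 1L)
    to   <- vapply(parts, `[`, character(1), 2L)
    wchr <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "1",
                   character(1))
    w <- suppressWarnings(as.numeric(wchr))
    if (anyNA(w))
        stop(sprintf("%s: non-numeric edge weight in line '%s'",
                     path, lines[which(is.na(w))[1]]), call. = FALSE)
    if (any(w < 0 | w > 1000))
        stop(sprintf("%s: edge weight out of range [0, 1000] in line '%s'",
                     path, lines[which(w < 0 | w > 1000)[1]]), call. = FALSE)
    w <- ifelse(w > 1, w / 1000, w)   # STRING combined scores -> probabilities
    loops <- sum(from == to)
    key <- paste(pmin(from, to), pmax(from, to), sep = "\r")
    dups <- sum(duplicated(key[from != to]))
    if (loops > 0)
        message(sprintf("%s: dropped %d self-loop(s)", networkId, loops))
    if (dups > 0)
        message(sprintf("%s: collapsed %d duplicate edge(s) (max weight kept)",
                        networkId, dups))
    PPINetwork(networkId, data.frame(from = from, to = to, weight = w,
                                     stringsAsFactors = FALSE))
}

#' Write a PPI network as a weighted edge-list file
#'
#' Inverse of [readPPINetwork()]: tab-separated `from to weight` lines,
#' weights printed with six decimals.  Isolated nodes are written as
#' commented `# node` lines so that the file documents them without
#' breaking the edge-list dialect.
#'
#' @param network a [PPINetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeNetwork <- function(network, path) {
    e <- interactions(network)
    lines <- sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight)
    deg <- igraph::degree(interactionGraph(network))
    isolated <- names(deg)[deg == 0]
    if (length(isolated))
        lines <- c(lines, paste0("# isolated: ", isolated))
    writeLines(lines, path)
    invisible(path)
}
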