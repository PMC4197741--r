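#' @include scoring.R
NULL

#' Write an alignment result file
#'
#' Each local alignment is stored as one text file with three sections: a
#' header (networks, size, density, ISC), one block per network listing
#' that network's aligned subgraph as a weighted edge list, and a mapping
#' section with one line per row giving the aligned proteins
#' tab-separated in network order.
#'
#' @inheritParams localDensity
#' @param path output file path.
#' @return the path, invisibly.
#' @seealso [readAlignment()] for the inverse.
#' @export
writeAlignment <- function(alignment, networks, path) {
    methods::validObject(alignment)
    nets <- .netsByIds(networks, alignment@networks)
    lines <- c(
        "# local alignment",
        paste0("# networks:\t", paste(alignment@networks, collapse = "\t")),
        sprintf("# size:\t%d", nrow(alignment@rows)),
        sprintf("# density:\t%.6f", localDensity(alignment, networks)),
        sprintf("# isc:\t%.2f", iscScore(alignment, networks)))
    for (i in seq_along(nets)) {
        lines <- c(lines, paste0("# subgraph\t", alignment@networks[i]))
        sg <- igraph::induced_subgraph(interactionGraph(nets[[i]]),
                                       alignment@rows[, i])
        if (igraph::ecount(sg) > 0) {
            e <- igraph::as_data_frame(sg, what = "edges")
            lines <- c(lines, sprintf("%s\t%s\t%.6f", e$from, e$to, e$weight))
        }
    }
    lines <- c(lines, "# mapping",
               apply(alignment@rows, 1, paste, collapse = "\t"))
    writeLines(lines, path)
    invisible(path)
}

#' Read an alignment result file
#'
#' Parses a file written by [writeAlignment()].  The returned
#' [Alignment-class] carries the parsed header values and per-network
#' subgraph edge tables in its `metadata` (`density`, `isc`,
#' `subgraphs`).
#'
#' @param path path to an alignment file.
#' @return an [Alignment-class].
#' @export
readAlignment <- function(path) {
    if (!file.exists(path))
        stop("cannot read file: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    nets <- NULL; density <- NA_real_; isc <- NA_real_
    subgraphs <- list()
    mapping <- character()
    section <- "header"
    current <- NULL
    for (ln in lines) {
        if (startsWith(ln, "#")) {
            body <- trimws(sub("^#", "", ln))
            if (startsWith(body, "networks:")) {
                nets <- strsplit(body, "\t")[[1]][-1]
            } else if (startsWith(body, "density:")) {
                density <- as.numeric(strsplit(body, "\t")[[1]][2])
            } else if (startsWith(body, "isc:")) {
                isc <- as.numeric(strsplit(body, "\t")[[1]][2])
            } else if (startsWith(body, "subgraph")) {
                current <- strsplit(body, "\t")[[1]][2]
                section <- "subgraph"
                subgraphs[[current]] <-
                    data.frame(from = character(), to = character(),
                               weight = numeric(), stringsAsFactors = FALSE)
            } else if (identical(body, "mapping")) {
                section <- "mapping"
            }
            next
        }
        if (section == "subgraph") {
            f <- strsplit(ln, "\t")[[1]]
            subgraphs[[current]] <- rbind(
                subgraphs[[current]],
                data.frame(from = f[1], to = f[2],
                           weight = as.numeric(f[3]),
                           stringsAsFactors = FALSE))
        } else if (section == "mapping") {
            mapping <- c(mapping, ln)
        }
    }
    if (is.null(nets) || length(mapping) == 0)
        stop(path, ": not a valid alignment file", call. = FALSE)
    rows <- do.call(rbind, strsplit(mapping, "\t"))
    Alignment(nets, rows,
              metadata = list(density = density, isc = isc,
                              subgraphs = subgraphs))
}
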