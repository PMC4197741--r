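#' @include AllClasses.R
NULL

#' @export
setGeneric("networkId", function(x) standardGeneric("networkId"))

#' @export
setGeneric("nodes", function(x, ...) standardGeneric("nodes"))

#' @export
setGeneric("interactionGraph",
    function(x) standardGeneric("interactionGraph"))

#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))

#' @export
setGeneric("similarityMode", function(x) standardGeneric("similarityMode"))

#' @export
setGeneric("pairScore", function(x, a, b) standardGeneric("pairScore"))

#' @export
setGeneric("alignmentRows", function(x) standardGeneric("alignmentRows"))

#' @export
setGeneric("alignedNetworks", function(x) standardGeneric("alignedNetworks"))

#' @export
setGeneric("alignmentSize", function(x) standardGeneric("alignmentSize"))

#' @export
setGeneric("descriptions", function(x) standardGeneric("descriptions"))

#' @export
setGeneric("goTerms", function(x, protein) standardGeneric("goTerms"))
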