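#' @name netcrit-generics
#' @title Generics for netcrit classes
#' @param x a netcrit object.
#' @param ... further arguments for methods.
#' @keywords internal
NULL

#' @rdname netcrit-generics
#' @export
setGeneric("genes", function(x, ...) standardGeneric("genes"))

#' @rdname netcrit-generics
#' @export
setGeneric("edges", function(x, ...) standardGeneric("edges"))

#' @rdname netcrit-generics
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))

#' @rdname netcrit-generics
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname netcrit-generics
#' @export
setGeneric("nodeDegrees", function(x, ...) standardGeneric("nodeDegrees"))

#' @rdname netcrit-generics
#' @export
setGeneric("groups", function(x, ...) standardGeneric("groups"))

#' @rdname netcrit-generics
#' @export
setGeneric("universe", function(x) standardGeneric("universe"))

#' @rdname netcrit-generics
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname netcrit-generics
#' @export
setGeneric("multifunctionality", function(x) {
    standardGeneric("multifunctionality")
})

#' @rdname netcrit-generics
#' @export
setGeneric("mapScore", function(x) standardGeneric("mapScore"))

#' @rdname netcrit-generics
#' @export
setGeneric("apScores", function(x) standardGeneric("apScores"))

#' @rdname netcrit-generics
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))

#' @rdname netcrit-generics
#' @export
setGeneric("edgeTally", function(x) standardGeneric("edgeTally"))

#' @rdname netcrit-generics
#' @export
setGeneric("selectedCount", function(x) standardGeneric("selectedCount"))

#' @rdname netcrit-generics
#' @export
setGeneric("calibrationStats", function(x) {
    standardGeneric("calibrationStats")
})

#' @rdname netcrit-generics
#' @export
setGeneric("predictedPairs", function(x) standardGeneric("predictedPairs"))
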