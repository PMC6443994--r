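#' @rdname edgeKeys
#' @export
setGeneric("edgeKeys", function(x, ...) standardGeneric("edgeKeys"))

#' @rdname tissueLabel
#' @export
setGeneric("tissueLabel", function(x) standardGeneric("tissueLabel"))

#' @rdname numEdges
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname numNodes
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname nodeNames
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname edgeTable
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
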