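#' @rdname Structure-class
#' @param object,x An object.
#' @export
setGeneric("structureId", function(x) standardGeneric("structureId"))

#' @rdname Structure-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname Structure-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname RIN-class
#' @export
setGeneric("nodeTable", function(x) standardGeneric("nodeTable"))

#' @rdname RIN-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname RIN-class
#' @export
setGeneric("rinMetadata", function(x) standardGeneric("rinMetadata"))

#' Convert a RIN to an igraph graph
#'
#' Returns the undirected \pkg{igraph} representation of a network; node
#' attributes \code{kind}, \code{chain} and \code{interface} are carried
#' over as vertex attributes.
#'
#' @param x A [RIN-class].
#' @return An \pkg{igraph} graph.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname CentralityResult-class
#' @export
setGeneric("centralityTable", function(x) standardGeneric("centralityTable"))

#' @rdname CentralityResult-class
#' @export
setGeneric("centralityMethod", function(x) standardGeneric("centralityMethod"))

#' Central nodes of a centrality analysis
#'
#' Nodes whose Z-score is greater than or equal to the cutoff (inclusive;
#' default 2) are classified as central.
#'
#' @param x A [CentralityResult-class].
#' @param threshold Z-score cutoff, default 2.
#' @return Character vector of node labels, sorted by decreasing Z.
#' @export
setGeneric("centralNodes", function(x, threshold = 2) standardGeneric("centralNodes"))

#' @rdname DifferentialReport-class
#' @param method \code{"RCA"} or \code{"BCA"}.
#' @export
setGeneric("addedCentral", function(x, method) standardGeneric("addedCentral"))

#' @rdname DifferentialReport-class
#' @export
setGeneric("lostCentral", function(x, method) standardGeneric("lostCentral"))
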