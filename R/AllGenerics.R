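#' Network accessors
#'
#' Accessor generics shared by [AffinityNetwork-class] and
#' [CoRegulatoryNetwork-class]: node sets, the arc table, node/arc counts
#' and the operon -> category map.
#'
#' @param x a network object.
#' @return `tfNodes`/`operonNodes` return character vectors, `arcs` the arc
#'   data.frame, `nodeCount`/`arcCount` integers, `categoryMap` a named
#'   list.
#' @name network-accessors
#' @aliases tfNodes operonNodes arcs nodeCount arcCount categoryMap
#' @examples
#' net <- plantNetwork(nTfFamilies = 5, nMetabolicOperons = 4,
#'                     categories = c(catA = 2, catB = 2), seed = 1)$network
#' nodeCount(net)
#' head(arcs(net))
NULL

#' @rdname network-accessors
#' @export
setGeneric("tfNodes", function(x) standardGeneric("tfNodes"))
#' @rdname network-accessors
#' @export
setGeneric("operonNodes", function(x) standardGeneric("operonNodes"))
#' @rdname network-accessors
#' @export
setGeneric("arcs", function(x) standardGeneric("arcs"))
#' @rdname network-accessors
#' @export
setGeneric("nodeCount", function(x) standardGeneric("nodeCount"))
#' @rdname network-accessors
#' @export
setGeneric("arcCount", function(x) standardGeneric("arcCount"))
#' @rdname network-accessors
#' @export
setGeneric("categoryMap", function(x) standardGeneric("categoryMap"))

for (cls in c("AffinityNetwork", "CoRegulatoryNetwork")) {
  setMethod("tfNodes", cls, function(x) x@tfNodes)
  setMethod("operonNodes", cls, function(x) x@operonNodes)
  setMethod("arcs", cls, function(x) x@arcs)
  setMethod("nodeCount", cls, function(x)
    length(x@tfNodes) + length(x@operonNodes))
  setMethod("arcCount", cls, function(x) nrow(x@arcs))
  setMethod("categoryMap", cls, function(x) x@categories)
}
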