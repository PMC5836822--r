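#' @import methods
NULL

#' Node identifiers of a network object
#'
#' @param x a \linkS4class{GlobalNetwork}, \linkS4class{Subnetwork} or
#'   \linkS4class{SyntheticWorld}.
#' @return Character vector of node IDs.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edge table of a network object
#'
#' @param x a \linkS4class{GlobalNetwork} or \linkS4class{Subnetwork}.
#' @return A data.frame with columns \code{a}, \code{b}, \code{type},
#'   \code{coarse} and (when scored) \code{score}; one row per typed edge,
#'   endpoints in canonical (sorted) order.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Number of (typed) links
#'
#' For a \linkS4class{Subnetwork} this is the test statistic: the number of
#' typed links with both endpoints inside the analysed set, under the active
#' coarse type filter.
#'
#' @param x a network object.
#' @return Non-negative integer.
#' @export
setGeneric("linkCount", function(x) standardGeneric("linkCount"))

#' Active coarse interaction-type filter
#'
#' @param x a \linkS4class{Subnetwork}.
#' @return A string: one of the coarse groups or \code{"all_types"}.
#' @export
setGeneric("coarseFilter", function(x) standardGeneric("coarseFilter"))

#' Mapped node IDs of a gene set
#'
#' @param x a \linkS4class{GeneSet}.
#' @return Character vector of node IDs present in the global network.
#' @export
setGeneric("mappedNodes", function(x) standardGeneric("mappedNodes"))

#' Input IDs that could not be mapped into the network
#'
#' @param x a \linkS4class{GeneSet}.
#' @return Character vector (possibly empty).
#' @export
setGeneric("unmappedIds", function(x) standardGeneric("unmappedIds"))

#' Link counts of a null sample
#'
#' @param x a \linkS4class{NullSample}.
#' @return Integer vector of induced link counts, one per random network.
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))

#' Area under a ROC curve
#'
#' @param x a \linkS4class{ROCCurve}.
#' @return AUC in [0, 1] (trapezoidal rule; equals the tie-corrected
#'   Mann-Whitney statistic).
#' @export
setGeneric("aucValue", function(x) standardGeneric("aucValue"))
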