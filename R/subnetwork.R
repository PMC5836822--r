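# Subnetwork reconstruction: the induced subgraph of the analysed set, with
# optional filtering to one coarse interaction type, plus per-node summaries
# (degree ranking and the specificity rate).

# indices of net edges with both endpoints inside nodeIdx (integer indices)
.inducedEdgeIdx <- function(net, nodeIdx) {
  inSet <- logical(length(net@nodes))
  inSet[nodeIdx] <- TRUE
  which(inSet[net@edgeA] & inSet[net@edgeB])
}

#' Reconstruct the induced subnetwork of a gene set
#'
#' Keeps exactly the global-network edges with both endpoints in the set
#' (intra-set semantics; links leaving the set are never counted). The
#' result carries the unfiltered \code{"all_types"} view; apply
#' \code{\link{filterByType}} afterwards to restrict to one coarse group.
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param gs a \linkS4class{GeneSet} or character vector of node IDs.
#' @return A \linkS4class{Subnetwork}.
#' @examples
#' net <- globalNetwork(c("A","B","C","D","A"), c("B","C","D","A","C"))
#' linkCount(extractSubnetwork(net, c("A","B","C")))  # AB, BC, AC -> 3
#' @export
extractSubnetwork <- function(net, gs) {
  stopifnot(is(net, "GlobalNetwork"))
  members <- if (is(gs, "GeneSet")) gs@mappedNodes else unique(as.character(gs))
  if (!length(members)) stop("empty gene set", call. = FALSE)
  if (!all(members %in% net@nodes))
    stop("gene set contains nodes absent from the network", call. = FALSE)
  members <- sort(members)
  nodeIdx <- match(members, net@nodes)
  keep <- .inducedEdgeIdx(net, nodeIdx)
  new("Subnetwork", nodes = members,
      edgeA = match(net@nodes[net@edgeA[keep]], members),
      edgeB = match(net@nodes[net@edgeB[keep]], members),
      edgeType = net@edgeType[keep], edgeCoarse = net@edgeCoarse[keep],
      edgeScore = net@edgeScore[keep], scored = net@scored,
      metadata = list(), coarseFilter = "all_types")
}

#' Restrict a subnetwork to one coarse interaction type
#'
#' \code{"all_types"} is a no-op (the generalized view, in which any fine
#' link type counts). The node set is unchanged; only edges of the requested
#' coarse group survive.
#'
#' @param sub an unfiltered \linkS4class{Subnetwork}.
#' @param coarse a coarse group name (see \code{\link{coarseGroupLevels}})
#'   or \code{"all_types"}.
#' @return A \linkS4class{Subnetwork}.
#' @export
filterByType <- function(sub, coarse = "all_types") {
  stopifnot(is(sub, "Subnetwork"))
  .checkCoarse(coarse)
  if (coarse == "all_types") return(sub)
  if (sub@coarseFilter != "all_types")
    stop("subnetwork is already filtered (", sub@coarseFilter, ")",
         call. = FALSE)
  keep <- which(sub@edgeCoarse == coarse)
  initialize(sub, edgeA = sub@edgeA[keep], edgeB = sub@edgeB[keep],
             edgeType = sub@edgeType[keep], edgeCoarse = sub@edgeCoarse[keep],
             edgeScore = sub@edgeScore[keep], coarseFilter = coarse)
}

# typed-link degree of every node of `net` under a coarse filter,
# as a named integer vector
.typedDegrees <- function(net, coarse = "all_types") {
  keep <- if (coarse == "all_types") seq_along(net@edgeA)
          else which(net@edgeCoarse == coarse)
  stats::setNames(
    tabulate(c(net@edgeA[keep], net@edgeB[keep]), nbins = length(net@nodes)),
    net@nodes)
}

#' Specificity rate of a node
#'
#' SR = (links of the node inside the analysed subnetwork) / (links of the
#' node in the global network), both counted under the subnetwork's active
#' coarse filter. SR close to 1 marks a node whose interactions are
#' concentrated in the analysed process.
#'
#' @param sub a \linkS4class{Subnetwork}.
#' @param net the \linkS4class{GlobalNetwork} it was extracted from.
#' @param node a node ID inside \code{sub}.
#' @return A number in [0, 1].
#' @export
specificityRate <- function(sub, net, node) {
  stopifnot(is(sub, "Subnetwork"), is(net, "GlobalNetwork"),
            length(node) == 1L)
  if (!(node %in% sub@nodes))
    stop("node '", node, "' is not in the subnetwork", call. = FALSE)
  globalDeg <- .typedDegrees(net, sub@coarseFilter)[node]
  if (is.na(globalDeg) || globalDeg == 0L)
    stop("node '", node, "' has no links in the global network under ",
         "filter '", sub@coarseFilter, "'; SR is undefined", call. = FALSE)
  localDeg <- .typedDegrees(sub, "all_types")[node]  # sub already filtered
  unname(localDeg / globalDeg)
}

#' Rank subnetwork nodes by degree or specificity rate
#'
#' @param sub a \linkS4class{Subnetwork}.
#' @param by \code{"degree"} (typed links inside the subnetwork) or
#'   \code{"specificity_rate"}.
#' @param net required for \code{by = "specificity_rate"}: the global
#'   network supplying the denominators.
#' @return data.frame(node, value), descending by value; ties broken
#'   lexicographically by node ID.
#' @export
rankNodes <- function(sub, by = c("degree", "specificity_rate"), net = NULL) {
  by <- match.arg(by)
  stopifnot(is(sub, "Subnetwork"), length(sub@nodes) > 0)
  localDeg <- .typedDegrees(sub, "all_types")
  value <- if (by == "degree") localDeg else {
    stopifnot(is(net, "GlobalNetwork"))
    globalDeg <- .typedDegrees(net, sub@coarseFilter)[names(localDeg)]
    if (any(globalDeg == 0L, na.rm = TRUE))
      stop("specificity rate undefined for node(s) with no global links ",
           "under filter '", sub@coarseFilter, "'", call. = FALSE)
    localDeg / globalDeg
  }
  o <- order(-value, names(value))
  data.frame(node = names(value)[o], value = unname(value)[o],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a subnetwork as TSV plus a JSON summary
#'
#' @param sub a \linkS4class{Subnetwork}.
#' @param prefix output path prefix; writes \code{<prefix>.tsv} and
#'   \code{<prefix>.json}.
#' @return Character vector of the two paths, invisibly.
#' @export
writeSubnetwork <- function(sub, prefix) {
  tsv <- paste0(prefix, ".tsv"); json <- paste0(prefix, ".json")
  writeEdgeList(sub, tsv)
  perCoarse <- as.list(table(factor(sub@edgeCoarse,
                                    levels = coarseGroupLevels())))
  jsonlite::write_json(
    list(nodes = length(sub@nodes), link_count = linkCount(sub),
         coarse_filter = sub@coarseFilter,
         links_per_coarse_group = perCoarse),
    json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
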