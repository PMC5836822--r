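#' GlobalNetwork: a typed, optionally scored, undirected multigraph
#'
#' The universe against which gene-set subnetworks are reconstructed and from
#' which degree-matched random node sets are drawn. Edges are undirected and
#' stored canonically (first endpoint sorts before the second); a pair of
#' nodes may be linked by several edges of different fine types, and each
#' (pair, fine type) combination occurs at most once. Self-loops are not
#' representable.
#'
#' @slot nodes character vector of node IDs, sorted, unique.
#' @slot edgeA,edgeB integer indices into \code{nodes}; \code{edgeA < edgeB}.
#' @slot edgeType character fine type label per edge.
#' @slot edgeCoarse character coarse group per edge (derived from
#'   \code{edgeType} via \code{\link{coarseGroup}}).
#' @slot edgeScore integer confidence score 0-1000 per edge, or \code{NA}
#'   throughout for unscored networks.
#' @slot scored logical: do all edges carry a score?
#' @slot metadata list of provenance notes (e.g. dropped self-loop count).
#' @export
setClass("GlobalNetwork", representation(
  nodes = "character",
  edgeA = "integer",
  edgeB = "integer",
  edgeType = "character",
  edgeCoarse = "character",
  edgeScore = "integer",
  scored = "logical",
  metadata = "list"
))

setValidity("GlobalNetwork", function(object) {
  n <- length(object@nodes)
  m <- length(object@edgeA)
  msg <- character(0)
  if (anyDuplicated(object@nodes)) msg <- c(msg, "node IDs must be unique")
  if (is.unsorted(object@nodes)) msg <- c(msg, "node IDs must be sorted")
  if (length(object@edgeB) != m || length(object@edgeType) != m ||
      length(object@edgeCoarse) != m || length(object@edgeScore) != m)
    msg <- c(msg, "edge slots must have equal length")
  if (m > 0) {
    if (any(object@edgeA < 1L) || any(object@edgeB > n))
      msg <- c(msg, "edge endpoints out of range")
    if (any(object@edgeA == object@edgeB))
      msg <- c(msg, "self-loops are not allowed")
    if (any(object@edgeA > object@edgeB))
      msg <- c(msg, "edges must be canonically ordered (edgeA < edgeB)")
    key <- paste(object@edgeA, object@edgeB, object@edgeType)
    if (anyDuplicated(key))
      msg <- c(msg, "at most one edge per (node pair, fine type)")
  }
  if (length(object@scored) != 1L)
    msg <- c(msg, "'scored' must be a single logical")
  else if (object@scored && m > 0 && anyNA(object@edgeScore))
    msg <- c(msg, "scored network has NA scores")
  if (length(msg)) msg else TRUE
})

#' Construct a GlobalNetwork from edge vectors
#'
#' Canonicalizes endpoint order, drops self-loops (counted in
#' \code{metadata$droppedSelfLoops}) and collapses duplicate
#' (pair, fine type) rows keeping the maximum score.
#'
#' @param a,b character endpoint IDs.
#' @param type character fine interaction-type labels (recycled if length 1).
#' @param score optional integer scores 0-1000; \code{NULL} for unscored.
#' @param extraNodes node IDs to include even when isolated.
#' @return A \linkS4class{GlobalNetwork}.
#' @examples
#' net <- globalNetwork(c("A", "B"), c("B", "C"), "interaction")
#' linkCount(net)
#' @export
globalNetwork <- function(a, b, type = "interaction", score = NULL,
                          extraNodes = character(0)) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  type <- rep_len(as.character(type), length(a))
  if (is.null(score)) {
    scored <- FALSE
    score <- rep(NA_integer_, length(a))
  } else {
    scored <- TRUE
    score <- rep_len(as.integer(score), length(a))
  }
  self <- a == b
  nSelf <- sum(self)
  if (nSelf > 0) {
    a <- a[!self]; b <- b[!self]; type <- type[!self]; score <- score[!self]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  nodes <- sort(unique(c(a, b, as.character(extraNodes))))
  ai <- match(a, nodes); bi <- match(b, nodes)
  # collapse duplicates keeping max score
  key <- paste(ai, bi, type)
  if (anyDuplicated(key)) {
    o <- order(key, -ifelse(is.na(score), -1L, score))
    keep <- o[!duplicated(key[o])]
    keep <- sort(keep)
    ai <- ai[keep]; bi <- bi[keep]; type <- type[keep]; score <- score[keep]
  }
  new("GlobalNetwork", nodes = nodes, edgeA = ai, edgeB = bi,
      edgeType = type, edgeCoarse = coarseGroup(type),
      edgeScore = score, scored = scored,
      metadata = list(droppedSelfLoops = nSelf))
}

#' Subnetwork: the induced, type-filtered network of a gene set
#'
#' Inherits the edge representation of \linkS4class{GlobalNetwork}; the node
#' slot holds the full analysed set (including isolated members) and
#' \code{coarseFilter} records the active interaction-type filter. The link
#' count of this object is the observed test statistic.
#'
#' @slot coarseFilter a coarse group name or \code{"all_types"}.
#' @export
setClass("Subnetwork", contains = "GlobalNetwork",
         representation(coarseFilter = "character"))

setValidity("Subnetwork", function(object) {
  msg <- character(0)
  if (length(object@coarseFilter) != 1L ||
      !(object@coarseFilter %in% coarseGroupLevels(withAllTypes = TRUE)))
    msg <- c(msg, "invalid coarseFilter")
  else if (object@coarseFilter != "all_types" &&
           length(object@edgeCoarse) > 0 &&
           any(object@edgeCoarse != object@coarseFilter))
    msg <- c(msg, "edges outside the active coarse filter")
  if (length(msg)) msg else TRUE
})

#' GeneSet: an input ID list resolved against a global network
#'
#' @slot rawIds the IDs as supplied (order and duplicates preserved).
#' @slot mappedNodes unique node IDs present in the network.
#' @slot unmappedIds supplied IDs that could not be resolved.
#' @export
setClass("GeneSet", representation(
  rawIds = "character",
  mappedNodes = "character",
  unmappedIds = "character"
))

setValidity("GeneSet", function(object) {
  if (anyDuplicated(object@mappedNodes))
    "mappedNodes must be unique" else TRUE
})

#' DegreeIndex: global-network nodes bucketed by exact degree
#'
#' Degree is the generalized all-types degree: the number of typed links
#' incident to the node after any score thresholding and before coarse type
#' filtering. Nodes of degree 0 are excluded from the buckets (they are not
#' part of the sampling universe).
#'
#' @slot degrees named integer vector over all nodes.
#' @slot buckets named list, \code{buckets[[as.character(d)]]} = node IDs of
#'   degree \code{d >= 1}, in sorted order.
#' @export
setClass("DegreeIndex", representation(
  degrees = "integer",
  buckets = "list"
))

#' NullSample: link counts of degree-matched random networks
#'
#' @slot counts integer link counts, one per random network.
#' @slot nNetworks number of random networks.
#' @slot seed RNG seed used.
#' @slot policy list describing the sampling policy (coarse filter, set size,
#'   fallback substitutions performed).
#' @export
setClass("NullSample", representation(
  counts = "integer",
  nNetworks = "integer",
  seed = "integer",
  policy = "list"
))

setValidity("NullSample", function(object) {
  msg <- character(0)
  if (length(object@counts) != object@nNetworks)
    msg <- c(msg, "length(counts) != nNetworks")
  if (length(object@counts) && any(object@counts < 0))
    msg <- c(msg, "negative counts")
  if (length(msg)) msg else TRUE
})

#' EnrichmentResult: the outcome of one enrichment test
#'
#' @slot observed induced link count of the analysed subnetwork.
#' @slot nullMean,nullSd sample mean and (n-1) standard deviation of the
#'   null link counts.
#' @slot pT upper-tail normal-approximation p-value.
#' @slot pPerm add-one Monte-Carlo permutation p-value (\code{NA} if not
#'   computed).
#' @slot pRoc empirical ROC p-value against a negative panel (\code{NA} if
#'   no panel was supplied).
#' @slot edgeless TRUE when both the analysed network and every random
#'   network had zero links (p fixed at 0.5).
#' @slot underflow TRUE when \code{pT} underflowed to exactly 0.
#' @slot coarse active interaction-type filter.
#' @slot mode "t" or "permutation".
#' @slot nNetworks,seed null-sample size and seed.
#' @slot nullSample the \linkS4class{NullSample} used (kept for audit).
#' @export
setClass("EnrichmentResult", representation(
  observed = "integer",
  nullMean = "numeric",
  nullSd = "numeric",
  pT = "numeric",
  pPerm = "numeric",
  pRoc = "numeric",
  edgeless = "logical",
  underflow = "logical",
  coarse = "character",
  mode = "character",
  nNetworks = "integer",
  seed = "integer",
  nullSample = "NullSample"
))

setValidity("EnrichmentResult", function(object) {
  msg <- character(0)
  ps <- c(object@pT, object@pPerm, object@pRoc)
  ps <- ps[!is.na(ps)]
  if (length(ps) && (any(ps < 0) || any(ps > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (isTRUE(object@edgeless)) {
    if (object@observed != 0L) msg <- c(msg, "edgeless result with links")
    if (object@pT != 0.5) msg <- c(msg, "edgeless result must have pT == 0.5")
  }
  if (length(msg)) msg else TRUE
})

#' ROCCurve: receiver operating characteristic of the score 1 - p
#'
#' Points run from (0,0) to (1,1); tied scores are grouped into single
#' threshold steps, so panels with many identical p-values (typically the
#' edgeless ones, all at p = 0.5) produce diagonal segments.
#'
#' @slot fpr,tpr coordinates of the curve.
#' @slot auc trapezoidal area under the curve.
#' @slot nPos,nNeg panel sizes.
#' @export
setClass("ROCCurve", representation(
  fpr = "numeric",
  tpr = "numeric",
  auc = "numeric",
  nPos = "integer",
  nNeg = "integer"
))

setValidity("ROCCurve", function(object) {
  msg <- character(0)
  if (length(object@fpr) != length(object@tpr))
    msg <- c(msg, "fpr/tpr length mismatch")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
    msg <- c(msg, "ROC points must be non-decreasing")
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc outside [0, 1]")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a generated benchmark universe
#'
#' @slot net the generated \linkS4class{GlobalNetwork}.
#' @slot modules named list of character vectors: planted functional modules
#'   (ground-truth positives).
#' @slot annotations named list node ID -> character vector of process IDs;
#'   every planted module is recorded as its own process.
#' @slot pubCounts named integer vector of simulated publication counts.
#' @slot config the generating configuration (echoed).
#' @export
setClass("SyntheticWorld", representation(
  net = "GlobalNetwork",
  modules = "list",
  annotations = "list",
  pubCounts = "integer",
  config = "list"
))

setValidity("SyntheticWorld", function(object) {
  msg <- character(0)
  mem <- unlist(object@modules, use.names = FALSE)
  if (length(mem) && !all(mem %in% object@net@nodes))
    msg <- c(msg, "module members must be network nodes")
  if (length(object@modules) &&
      !all(names(object@modules) %in%
           unique(unlist(object@annotations, use.names = FALSE))))
    msg <- c(msg, "every module must appear in the annotations")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "GlobalNetwork", function(x) x@nodes)

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "SyntheticWorld", function(x) x@net@nodes)

#' @rdname edgeTable
#' @export
setMethod("edgeTable", "GlobalNetwork", function(x) {
  df <- data.frame(a = x@nodes[x@edgeA], b = x@nodes[x@edgeB],
                   type = x@edgeType, coarse = x@edgeCoarse,
                   stringsAsFactors = FALSE)
  if (x@scored) df$score <- x@edgeScore
  df
})

#' @rdname linkCount
#' @export
setMethod("linkCount", "GlobalNetwork", function(x) length(x@edgeA))

#' @rdname coarseFilter
#' @export
setMethod("coarseFilter", "Subnetwork", function(x) x@coarseFilter)

#' @rdname mappedNodes
#' @export
setMethod("mappedNodes", "GeneSet", function(x) x@mappedNodes)

#' @rdname unmappedIds
#' @export
setMethod("unmappedIds", "GeneSet", function(x) x@unmappedIds)

#' @rdname nullCounts
#' @export
setMethod("nullCounts", "NullSample", function(x) x@counts)

#' @rdname aucValue
#' @export
setMethod("aucValue", "ROCCurve", function(x) x@auc)

## ---- show methods ----

setMethod("show", "GlobalNetwork", function(object) {
  cat(class(object), "with", length(object@nodes), "nodes and",
      length(object@edgeA), "typed links",
      if (object@scored) "(scored)" else "(unscored)", "\n")
  tab <- sort(table(object@edgeCoarse), decreasing = TRUE)
  if (length(tab))
    cat("  coarse groups:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "Subnetwork", function(object) {
  cat("Subnetwork:", length(object@nodes), "nodes,",
      length(object@edgeA), "links, filter =", object@coarseFilter, "\n")
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet:", length(object@rawIds), "input IDs ->",
      length(object@mappedNodes), "mapped nodes,",
      length(object@unmappedIds), "unmapped\n")
})

setMethod("show", "NullSample", function(object) {
  cat("NullSample:", object@nNetworks, "random networks, mean count",
      signif(mean(object@counts), 4), "\n")
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult [", object@coarse, "]\n", sep = "")
  cat("  observed links:", object@observed,
      " null mean:", signif(object@nullMean, 4),
      " null sd:", signif(object@nullSd, 4), "\n")
  cat("  p (normal approx):", format(object@pT, digits = 4),
      if (object@underflow) "(underflow)" else "", "\n")
  if (!is.na(object@pPerm))
    cat("  p (permutation):  ", format(object@pPerm, digits = 4), "\n")
  if (!is.na(object@pRoc))
    cat("  p (empirical ROC):", format(object@pRoc, digits = 4), "\n")
  if (object@edgeless) cat("  edgeless network: p fixed at 0.5\n")
})

setMethod("show", "ROCCurve", function(object) {
  cat("ROCCurve:", object@nPos, "positives vs", object@nNeg,
      "negatives, AUC =", signif(object@auc, 4), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld:", length(object@net@nodes), "nodes,",
      length(object@net@edgeA), "links,",
      length(object@modules), "planted modules\n")
})
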