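# Degree-matched node-permutation null model. Random networks are built by
# replacing every analysed node with a uniformly chosen global-network node
# of identical generalized degree (typed multi-edges counted separately,
# after score thresholding, before coarse type filtering), without
# replacement across the replacement set, then taking the induced subgraph.
# Only labels relevant to the analysed set are permuted; the global network
# itself is never rewired.

#' Bucket global-network nodes by exact generalized degree
#'
#' @param net a \linkS4class{GlobalNetwork} (post score-thresholding).
#' @return A \linkS4class{DegreeIndex}. Nodes of degree 0 carry a degree
#'   entry but no bucket: they are outside the sampling universe.
#' @export
buildDegreeIndex <- function(net) {
  stopifnot(is(net, "GlobalNetwork"), length(net@nodes) > 0)
  deg <- .typedDegrees(net, "all_types")
  pos <- deg[deg >= 1L]
  new("DegreeIndex", degrees = deg,
      buckets = split(names(pos), pos))  # names sorted => deterministic order
}

# Group query degrees: list(degree=, k=, bucketIdx=) with buckets as integer
# node indices for the fast path.
.groupQuery <- function(queryNodes, idx, nodes) {
  qdeg <- idx@degrees[queryNodes]
  if (anyNA(qdeg))
    stop("query node(s) absent from the degree index", call. = FALSE)
  if (any(qdeg == 0L))
    stop("query node(s) with degree 0 have no sampling bucket: ",
         paste(utils::head(queryNodes[qdeg == 0L], 5), collapse = ", "),
         call. = FALSE)
  tab <- table(qdeg)
  degs <- as.integer(names(tab))
  list(degs = degs, k = as.integer(tab),
       buckets = lapply(as.character(degs),
                        function(d) match(idx@buckets[[d]], nodes)))
}

# One replicate with nearest-degree fallback (slow path; the fallback is
# unreachable when the query set is a subset of the indexed network, because
# each query node occupies its own bucket).
.sampleOneWithFallback <- function(grp, idx, nodes) {
  chosen <- integer(0)
  fallbacks <- 0L
  allDegs <- as.integer(names(idx@buckets))
  for (j in seq_along(grp$degs)) {
    d <- grp$degs[j]; k <- grp$k[j]
    pool <- setdiff(grp$buckets[[j]], chosen)
    while (length(pool) < k) {
      # nearest non-exhausted degree, smaller preferred on ties
      cand <- setdiff(allDegs, d)
      cand <- cand[order(abs(cand - d), cand)]
      found <- FALSE
      for (d2 in cand) {
        extra <- setdiff(match(idx@buckets[[as.character(d2)]], nodes),
                         c(chosen, pool))
        if (length(extra)) {
          take <- extra[sample.int(length(extra), 1L)]
          pool <- c(pool, take)
          fallbacks <- fallbacks + 1L
          found <- TRUE
          break
        }
      }
      if (!found)
        stop("global network too small for a degree-matched sample",
             call. = FALSE)
    }
    chosen <- c(chosen, pool[sample.int(length(pool), k)])
  }
  list(chosen = chosen, fallbacks = fallbacks)
}

#' Draw one degree-matched replacement node set
#'
#' Each analysed node is replaced by a node drawn uniformly from its degree
#' bucket (the original node itself is eligible); the whole replacement set
#' is sampled without replacement, so the random network has exactly as many
#' distinct vertices as the analysed one. If a bucket is exhausted, the
#' nearest non-exhausted degree substitutes (smaller degree preferred on
#' ties) and the substitution is counted on the \code{"fallbacks"}
#' attribute.
#'
#' @param gs a \linkS4class{GeneSet} or character vector of node IDs.
#' @param idx a \linkS4class{DegreeIndex}.
#' @param net the \linkS4class{GlobalNetwork} the index was built on.
#' @param seed optional integer seed.
#' @return Character vector of node IDs with attribute \code{fallbacks}.
#' @export
sampleMatchedNodeSet <- function(gs, idx, net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  members <- if (is(gs, "GeneSet")) gs@mappedNodes else unique(as.character(gs))
  grp <- .groupQuery(members, idx, net@nodes)
  res <- .sampleOneWithFallback(grp, idx, net@nodes)
  structure(net@nodes[res$chosen], fallbacks = res$fallbacks)
}

#' Link counts of degree-matched random networks
#'
#' Runs the full null recipe \code{n} times: draw a degree-matched
#' replacement set, reconstruct its induced subnetwork, apply the coarse
#' type filter, record the link count. Fully reproducible from \code{seed};
#' the global network object is never modified.
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param gs a \linkS4class{GeneSet} or character vector of node IDs.
#' @param coarse coarse type filter (\code{"all_types"} default).
#' @param n number of random networks (100 for the normal-approximation
#'   test; 1000 for the permutation variant).
#' @param seed integer seed.
#' @param idx optional precomputed \code{\link{buildDegreeIndex}} result
#'   (reuse it across many sets on one network).
#' @return A \linkS4class{NullSample}.
#' @export
generateNullCounts <- function(net, gs, coarse = "all_types", n = 100L,
                               seed = 1L, idx = NULL) {
  stopifnot(is(net, "GlobalNetwork"), n >= 1L)
  .checkCoarse(coarse)
  if (is.null(idx)) idx <- buildDegreeIndex(net)
  members <- if (is(gs, "GeneSet")) gs@mappedNodes else unique(as.character(gs))
  if (length(members) > length(net@nodes))
    stop("gene set larger than the global network", call. = FALSE)
  grp <- .groupQuery(members, idx, net@nodes)

  eKeep <- if (coarse == "all_types") seq_along(net@edgeA)
           else which(net@edgeCoarse == coarse)
  ea <- net@edgeA[eKeep]; eb <- net@edgeB[eKeep]

  set.seed(seed)
  counts <- integer(n)
  fallbacks <- 0L
  fastPath <- all(grp$k <= lengths(grp$buckets))
  if (fastPath) {
    mark <- integer(length(net@nodes))
    nb <- length(grp$buckets)
    for (i in seq_len(n)) {
      for (j in seq_len(nb)) {
        b <- grp$buckets[[j]]
        mark[b[sample.int(length(b), grp$k[j])]] <- i
      }
      counts[i] <- sum(mark[ea] == i & mark[eb] == i)
    }
  } else {
    mark <- integer(length(net@nodes))
    for (i in seq_len(n)) {
      res <- .sampleOneWithFallback(grp, idx, net@nodes)
      fallbacks <- fallbacks + res$fallbacks
      mark[res$chosen] <- i
      counts[i] <- sum(mark[ea] == i & mark[eb] == i)
    }
  }
  new("NullSample", counts = counts, nNetworks = as.integer(n),
      seed = as.integer(seed),
      policy = list(method = "degree_matched_node_permutation",
                    coarse = coarse, setSize = length(members),
                    fallbacks = fallbacks))
}

#' Serialize a NullSample to JSON
#'
#' @param ns a \linkS4class{NullSample}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNullSample <- function(ns, path) {
  jsonlite::write_json(
    list(counts = ns@counts, n_networks = ns@nNetworks, seed = ns@seed,
         policy = ns@policy),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
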