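# The four negative-control set models used to benchmark the test:
#   simply_random - uniform over nodes with at least one global link;
#   well_studied  - same, restricted to frequently published nodes;
#   go_based      - annotated nodes, no two sharing any process;
#   idd           - degree-matched replacement of a reference set
#                   (identical degree distribution).

#' Sample one negative-control gene set
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param model one of \code{"simply_random"}, \code{"well_studied"},
#'   \code{"go_based"}, \code{"idd"}.
#' @param size number of nodes to draw (ignored for \code{"idd"}, which
#'   matches the reference set).
#' @param idx optional precomputed \linkS4class{DegreeIndex}.
#' @param annotations node -> process table (required for
#'   \code{"go_based"}; see \code{\link{readAnnotations}}).
#' @param pubCounts named publication counts (required for
#'   \code{"well_studied"}).
#' @param minPublications publication threshold for \code{"well_studied"}
#'   (default 50, inclusive).
#' @param maxRetries restart budget for the \code{"go_based"} disjointness
#'   constraint.
#' @param referenceSet a \linkS4class{GeneSet} or node-ID vector
#'   (\code{"idd"} only).
#' @param seed optional integer seed.
#' @return A \linkS4class{GeneSet}.
#' @export
sampleNegative <- function(net, model = c("simply_random", "well_studied",
                                          "go_based", "idd"),
                           size = NULL, idx = NULL, annotations = NULL,
                           pubCounts = NULL, minPublications = 50L,
                           maxRetries = 100L, referenceSet = NULL,
                           seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(idx)) idx <- buildDegreeIndex(net)
  universe <- names(idx@degrees)[idx@degrees >= 1L]

  pick <- switch(model,
    simply_random = {
      .checkSize(size, universe, model)
      universe[sample.int(length(universe), size)]
    },
    well_studied = {
      if (is.null(pubCounts))
        stop("'well_studied' needs publication counts", call. = FALSE)
      pool <- intersect(universe,
                        names(pubCounts)[pubCounts >= minPublications])
      .checkSize(size, pool, model)
      pool[sample.int(length(pool), size)]
    },
    go_based = {
      if (is.null(annotations))
        stop("'go_based' needs an annotation table", call. = FALSE)
      pool <- intersect(universe, names(annotations))
      .checkSize(size, pool, model)
      .sampleProcessDisjoint(pool, annotations, size, maxRetries)
    },
    idd = {
      if (is.null(referenceSet))
        stop("'idd' needs a reference set", call. = FALSE)
      sampleMatchedNodeSet(referenceSet, idx, net)
    })
  new("GeneSet", rawIds = as.character(pick),
      mappedNodes = as.character(sort(pick)), unmappedIds = character(0))
}

.checkSize <- function(size, pool, model) {
  if (is.null(size) || size < 2L)
    stop("negative-control size must be >= 2", call. = FALSE)
  if (length(pool) < size)
    stop("universe for model '", model, "' has only ", length(pool),
         " nodes; cannot draw ", size, call. = FALSE)
}

# rejection sampling with restarts: draw nodes one at a time, skipping any
# candidate sharing a process with the current draw; restart when stuck
.sampleProcessDisjoint <- function(pool, annotations, size, maxRetries) {
  for (attempt in seq_len(max(1L, maxRetries))) {
    chosen <- character(0)
    used <- character(0)
    cand <- pool[sample.int(length(pool))]
    for (node in cand) {
      procs <- annotations[[node]]
      if (!length(procs) || any(procs %in% used)) next
      chosen <- c(chosen, node)
      used <- c(used, procs)
      if (length(chosen) == size) return(chosen)
    }
  }
  stop("could not draw ", size, " process-disjoint nodes within ",
       maxRetries, " attempts; the annotation structure may make the ",
       "constraint infeasible", call. = FALSE)
}

#' Build a negative panel matched in size to a positive panel
#'
#' One negative set per requested size, all drawn under the same model;
#' reproducible from \code{seed} (set i uses seed + i).
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param model negative-control model (see \code{\link{sampleNegative}}).
#' @param sizes integer vector: the positive panel's set sizes.
#' @param referenceSets for \code{"idd"}: list of reference sets, one per
#'   panel entry.
#' @param seed integer base seed.
#' @param ... forwarded to \code{\link{sampleNegative}}.
#' @return List of \linkS4class{GeneSet}s.
#' @export
buildNegativePanel <- function(net, model, sizes, referenceSets = NULL,
                               seed = 1L, ...) {
  if (!length(sizes)) stop("empty positive panel", call. = FALSE)
  idx <- buildDegreeIndex(net)
  lapply(seq_along(sizes), function(i)
    sampleNegative(net, model = model, size = sizes[i], idx = idx,
                   referenceSet = if (is.null(referenceSets)) NULL
                                  else referenceSets[[i]],
                   seed = as.integer(seed) + i, ...))
}
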