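# The enrichment statistics: normal-approximation (one-sided, upper tail)
# p-value from the moments of the null link counts, the add-one Monte-Carlo
# permutation p-value, the edgeless convention (p = 0.5 when the analysed
# network and every random network have zero links), the empirical ROC
# p-value against a negative panel, and Benjamini-Hochberg adjustment.

#' Upper-tail normal-approximation p-value
#'
#' Fits a normal distribution to the null link counts (sample mean and
#' sample standard deviation, n-1 denominator) and returns
#' P(X >= observed). When the null sample is constant (sd 0) the p-value
#' degenerates to 0, 0.5 or 1 by the position of the observed count; the
#' all-zero, observed-zero case is the edgeless convention p = 0.5.
#'
#' @param observed induced link count of the analysed subnetwork.
#' @param ns a \linkS4class{NullSample} (or integer vector of counts).
#' @return p-value in [0, 1].
#' @examples
#' tTestP(10, as.integer(c(4, 6, 5, 5)))
#' @export
tTestP <- function(observed, ns) {
  counts <- if (is(ns, "NullSample")) ns@counts else as.integer(ns)
  if (length(counts) < 2L)
    stop("need at least 2 null counts to fit the normal", call. = FALSE)
  mu <- mean(counts)
  sigma <- stats::sd(counts)
  if (sigma == 0) {
    if (observed > mu) return(0)
    if (observed < mu) return(1)
    return(0.5)
  }
  stats::pnorm(observed, mean = mu, sd = sigma, lower.tail = FALSE)
}

#' Add-one Monte-Carlo permutation p-value
#'
#' (number of null counts >= observed + 1) / (n + 1); never exactly zero.
#' The edgeless convention overrides the formula: an observed count of 0
#' against an all-zero null sample returns 0.5 (the naive estimator would
#' give ~1, which misrepresents a network about which the null carries no
#' information).
#'
#' @param observed induced link count of the analysed subnetwork.
#' @param ns a \linkS4class{NullSample} (or integer vector of counts).
#' @return p-value in (0, 1].
#' @export
permutationP <- function(observed, ns) {
  counts <- if (is(ns, "NullSample")) ns@counts else as.integer(ns)
  if (!length(counts)) stop("empty null sample", call. = FALSE)
  if (observed == 0L && all(counts == 0L)) return(0.5)
  (sum(counts >= observed) + 1) / (length(counts) + 1)
}

#' Empirical ROC p-value against a negative panel
#'
#' The proportion of negative-panel p-values less than or equal to the
#' analysed set's p-value (inclusive). This calibrates the possibly biased
#' normal-approximation p against sets known to be non-functional.
#'
#' @param observedP p-value of the analysed set.
#' @param negativePs p-values of the negative panel.
#' @return Proportion in [0, 1].
#' @export
empiricalRocP <- function(observedP, negativePs) {
  if (!length(negativePs)) stop("empty negative panel", call. = FALSE)
  mean(negativePs <= observedP)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate control over the p-values passed
#' in (m = length of the input), returned in input order.
#'
#' @param ps numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bhAdjust <- function(ps) {
  if (anyNA(ps) || any(ps < 0) || any(ps > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(ps, method = "BH")
}

#' Test a gene set for functional link enrichment
#'
#' The full procedure: reconstruct the induced subnetwork of the set,
#' filter it to the requested coarse interaction type, generate \code{n}
#' degree-matched node-permutation random networks, and compare link
#' counts. Mode \code{"t"} (default n = 100) reports the
#' normal-approximation p-value; mode \code{"permutation"} (default
#' n = 1000) additionally reports the add-one Monte-Carlo p-value. Query
#' nodes with no links anywhere in the global network are dropped with a
#' message (they are outside the sampling universe and cannot contribute
#' links).
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param gs a \linkS4class{GeneSet} or character vector of node IDs.
#' @param coarse coarse type filter (\code{"all_types"} default).
#' @param mode \code{"t"} or \code{"permutation"}.
#' @param n number of random networks; defaults to 100 (t) or 1000
#'   (permutation).
#' @param seed integer seed.
#' @param idx optional precomputed \linkS4class{DegreeIndex}.
#' @param negativePs optional numeric vector of negative-panel p-values;
#'   when supplied the empirical ROC p-value is reported too.
#' @return An \linkS4class{EnrichmentResult}.
#' @examples
#' net <- globalNetwork(c("A","B","C","A"), c("B","C","A","D"))
#' enrich(net, c("A", "B", "C"), n = 50, seed = 7)
#' @export
enrich <- function(net, gs, coarse = "all_types",
                   mode = c("t", "permutation"), n = NULL, seed = 1L,
                   idx = NULL, negativePs = NULL) {
  mode <- match.arg(mode)
  .checkCoarse(coarse)
  if (is.null(n)) n <- if (mode == "t") 100L else 1000L
  members <- if (is(gs, "GeneSet")) gs@mappedNodes else unique(as.character(gs))
  if (is.null(idx)) idx <- buildDegreeIndex(net)
  isolated <- members[idx@degrees[members] == 0L]
  if (length(isolated)) {
    message("dropping ", length(isolated),
            " node(s) with no links in the global network")
    members <- setdiff(members, isolated)
  }
  if (!length(members))
    stop("no query nodes with links in the global network", call. = FALSE)

  sub <- filterByType(extractSubnetwork(net, members), coarse)
  observed <- linkCount(sub)
  ns <- generateNullCounts(net, members, coarse = coarse, n = n,
                           seed = seed, idx = idx)
  edgeless <- observed == 0L && all(ns@counts == 0L)
  pT <- tTestP(observed, ns)
  pPerm <- if (mode == "permutation") permutationP(observed, ns) else NA_real_
  pRoc <- if (!is.null(negativePs)) empiricalRocP(pT, negativePs) else NA_real_
  new("EnrichmentResult",
      observed = as.integer(observed),
      nullMean = mean(ns@counts), nullSd = stats::sd(ns@counts),
      pT = pT, pPerm = pPerm, pRoc = pRoc,
      edgeless = edgeless, underflow = (pT == 0),
      coarse = coarse, mode = mode,
      nNetworks = as.integer(n), seed = as.integer(seed),
      nullSample = ns)
}

#' Serialize an EnrichmentResult to a plain list (for JSON/TSV output)
#'
#' @param x an \linkS4class{EnrichmentResult}.
#' @return Named list of scalars.
#' @export
resultAsList <- function(x) {
  stopifnot(is(x, "EnrichmentResult"))
  list(observed = x@observed, null_mean = x@nullMean, null_sd = x@nullSd,
       p_t = x@pT, p_perm = x@pPerm, p_roc = x@pRoc,
       edgeless = x@edgeless, underflow = x@underflow,
       type = x@coarse, mode = x@mode, n = x@nNetworks, seed = x@seed)
}
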