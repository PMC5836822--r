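# ROC/AUC benchmarking of the classifier score 1 - p on positive versus
# negative panels, sensitivity at fixed specificity, and the
# completeness-subsampling experiment (how detection degrades when only a
# fraction of a functional module is observed).

#' ROC curve from positive- and negative-panel p-values
#'
#' The classifier score is 1 - p. Tied scores are grouped into single
#' threshold steps, so a shared value (typically p = 0.5 from edgeless
#' networks in both panels) produces one diagonal segment rather than a
#' staircase. The AUC is the trapezoidal area, which for this construction
#' equals the tie-corrected (1/2 per tie) Mann-Whitney statistic.
#'
#' @param posPs p-values of the positive (functional) panel.
#' @param negPs p-values of the negative panel.
#' @return A \linkS4class{ROCCurve}.
#' @examples
#' aucValue(rocFromPvalues(c(0.001, 0.02), c(0.4, 0.9)))
#' @export
rocFromPvalues <- function(posPs, negPs) {
  if (!length(posPs) || !length(negPs))
    stop("both panels must be non-empty", call. = FALSE)
  score <- c(1 - posPs, 1 - negPs)
  isPos <- rep(c(TRUE, FALSE), c(length(posPs), length(negPs)))
  o <- order(score, decreasing = TRUE)
  score <- score[o]; isPos <- isPos[o]
  # one step per distinct score (ties grouped)
  last <- !duplicated(score, fromLast = TRUE)
  tp <- cumsum(isPos)[last]
  fp <- cumsum(!isPos)[last]
  tpr <- c(0, tp / length(posPs))
  fpr <- c(0, fp / length(negPs))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", fpr = fpr, tpr = tpr, auc = auc,
      nPos = length(posPs), nNeg = length(negPs))
}

#' Sensitivity at a given specificity
#'
#' Reads the curve at false-positive rate 1 - specificity, linearly
#' interpolating between curve points; at an exact curve x-coordinate the
#' highest achievable sensitivity is returned.
#'
#' @param roc a \linkS4class{ROCCurve}.
#' @param specificity target specificity in [0, 1].
#' @return Sensitivity (true-positive rate) in [0, 1].
#' @export
sensitivityAtSpecificity <- function(roc, specificity) {
  stopifnot(is(roc, "ROCCurve"), specificity >= 0, specificity <= 1)
  x <- 1 - specificity
  # collapse vertical segments to their top
  top <- rev(!duplicated(rev(roc@fpr)))
  fpr <- roc@fpr[top]; tpr <- roc@tpr[top]
  stats::approx(fpr, tpr, xout = x, rule = 2, ties = max)$y
}

#' Enrichment p-values for a panel of gene sets
#'
#' Convenience wrapper: one \code{\link{enrich}} run per set on a shared
#' degree index, reporting the normal-approximation p-value (or the
#' permutation p-value in permutation mode). Set i uses seed + i.
#'
#' @param net a \linkS4class{GlobalNetwork}.
#' @param sets list of \linkS4class{GeneSet}s or node-ID vectors.
#' @param coarse coarse type filter.
#' @param mode \code{"t"} or \code{"permutation"}.
#' @param n random networks per set (mode default when \code{NULL}).
#' @param seed integer base seed.
#' @param idx optional shared \linkS4class{DegreeIndex}.
#' @return Numeric vector of p-values.
#' @export
panelPvalues <- function(net, sets, coarse = "all_types", mode = "t",
                         n = NULL, seed = 1L, idx = NULL) {
  if (is.null(idx)) idx <- buildDegreeIndex(net)
  vapply(seq_along(sets), function(i) {
    r <- enrich(net, sets[[i]], coarse = coarse, mode = mode, n = n,
                seed = as.integer(seed) + i, idx = idx)
    if (mode == "permutation") r@pPerm else r@pT
  }, numeric(1))
}

#' Completeness-subsampling experiment
#'
#' For each module-size bin, a fixed number of members
#' (\code{subsampleSize}) is drawn from every planted module in the bin and
#' tested for enrichment against a size-matched simply-random negative
#' panel; the bin's ROC AUC is reported. Completeness is
#' \code{subsampleSize / module size}: bins of large modules probe the
#' regime where only a small fraction of the true process was observed.
#'
#' @param world a \linkS4class{SyntheticWorld} with modules in the
#'   requested bins.
#' @param subsampleSize members drawn per module (default 10).
#' @param bins list of \code{c(lo, hi)} inclusive module-size ranges.
#' @param nSets maximum modules used per bin.
#' @param nNull random networks per enrichment test.
#' @param mode \code{"t"} or \code{"permutation"}.
#' @param seed integer seed.
#' @return data.frame(bin_lo, bin_hi, n_sets, completeness, auc),
#'   one row per non-empty bin; empty bins are skipped with a warning.
#' @export
completenessExperiment <- function(world, subsampleSize = 10L,
                                   bins = list(c(10, 10), c(20, 22),
                                               c(40, 50), c(100, 200),
                                               c(400, 1000)),
                                   nSets = 20L, nNull = 100L, mode = "t",
                                   seed = 1L) {
  stopifnot(is(world, "SyntheticWorld"))
  net <- world@net
  idx <- buildDegreeIndex(net)
  sizes <- lengths(world@modules)
  rows <- list()
  for (b in seq_along(bins)) {
    lo <- bins[[b]][1]; hi <- bins[[b]][2]
    hit <- which(sizes >= lo & sizes <= hi & sizes >= subsampleSize)
    if (!length(hit)) {
      warning("no modules of size in [", lo, ", ", hi, "]; bin skipped")
      next
    }
    set.seed(as.integer(seed) + b)
    hit <- hit[seq_len(min(nSets, length(hit)))]
    posSets <- lapply(world@modules[hit], function(m)
      m[sample.int(length(m), subsampleSize)])
    negSets <- buildNegativePanel(net, "simply_random",
                                  rep(subsampleSize, length(posSets)),
                                  seed = as.integer(seed) + 1000L * b)
    posP <- panelPvalues(net, posSets, mode = mode, n = nNull,
                         seed = as.integer(seed) + 10000L * b, idx = idx)
    negP <- panelPvalues(net, negSets, mode = mode, n = nNull,
                         seed = as.integer(seed) + 20000L * b, idx = idx)
    rows[[length(rows) + 1L]] <- data.frame(
      bin_lo = lo, bin_hi = hi, n_sets = length(posSets),
      completeness = subsampleSize / mean(sizes[hit]),
      auc = aucValue(rocFromPvalues(posP, negP)))
  }
  do.call(rbind, rows)
}

#' Bootstrap confidence interval for an AUC
#'
#' Percentile bootstrap over panel members (both panels resampled with
#' replacement).
#'
#' @param posPs,negPs panel p-values.
#' @param nBoot bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return Named numeric: auc, lower, upper.
#' @export
aucBootstrapCI <- function(posPs, negPs, nBoot = 1000L, level = 0.95,
                           seed = 1L) {
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(i)
    aucValue(rocFromPvalues(sample(posPs, replace = TRUE),
                            sample(negPs, replace = TRUE))),
    numeric(1))
  qs <- stats::quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  c(auc = aucValue(rocFromPvalues(posPs, negPs)),
    lower = qs[1], upper = qs[2])
}
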