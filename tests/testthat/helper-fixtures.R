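# Fixtures shared across test files. Everything is built in code; no data
# files are read from disk except those a test itself writes to a tempdir.

# 5-node toy: edges AB, BC, CD, DA, AC (all "interaction")
toyNet <- function() {
  globalNetwork(c("A", "B", "C", "D", "A"),
                c("B", "C", "D", "A", "C"))
}

# mixed-type network on a triangle plus a pendant, for type filtering
typedNet <- function() {
  globalNetwork(
    a = c("A", "A", "B", "B", "C"),
    b = c("B", "B", "C", "C", "D"),
    type = c("interaction", "catalyze", "coexpression",
             "expression regulation", "activity upregulation"))
}

# star: hub H linked to nLeaves leaves; all leaves have degree 1, the hub
# degree nLeaves. Any degree-matched sample of leaves is edgeless.
starNet <- function(nLeaves = 10) {
  leaves <- sprintf("L%02d", seq_len(nLeaves))
  globalNetwork(rep("H", nLeaves), leaves)
}

# tiny enumerable world: 8 nodes, heterogeneous degrees, small buckets
tinyNet <- function() {
  globalNetwork(
    a = c("a", "a", "b", "c", "e", "e", "g"),
    b = c("b", "c", "c", "d", "f", "g", "h"))
}

# exact null distribution of the induced link count by full enumeration of
# all degree-matched assignments (uniform subset per degree bucket,
# independent across buckets) -- the brute-force oracle for the sampler
enumNullDistribution <- function(net, members, coarse = "all_types") {
  idx <- buildDegreeIndex(net)
  qdeg <- idx@degrees[members]
  stopifnot(all(qdeg >= 1))
  grps <- split(names(qdeg), qdeg)
  subsetChoices <- lapply(names(grps), function(d) {
    bucket <- idx@buckets[[d]]
    k <- length(grps[[d]])
    combn(bucket, k, simplify = FALSE)
  })
  grid <- subsetChoices[[1]]
  if (length(subsetChoices) > 1)
    for (j in 2:length(subsetChoices))
      grid <- unlist(lapply(grid, function(g)
        lapply(subsetChoices[[j]], function(s) c(g, s))), recursive = FALSE)
  counts <- vapply(grid, function(nodes)
    linkCount(filterByType(extractSubnetwork(net, nodes), coarse)),
    integer(1))
  counts  # each assignment equally likely
}

# a small benchmark world shared by several test files
smallWorld <- function(seed = 7, modules = list(
                         list(size = 15, extraEdgeProb = 0.5),
                         list(size = 20, extraEdgeProb = 0.4))) {
  generateWorld(syntheticWorldConfig(600, minDegree = 2, modules = modules,
                                     seed = seed))
}
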