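test_that("degree buckets reflect generalized multi-edge degrees", {
  tri <- globalNetwork(c("A", "B", "C"), c("B", "C", "A"))
  idx <- buildDegreeIndex(tri)
  expect_equal(idx@buckets, list(`2` = c("A", "B", "C")))

  path <- globalNetwork(c("A", "B"), c("B", "C"))
  idx2 <- buildDegreeIndex(path)
  expect_equal(idx2@buckets, list(`1` = c("A", "C"), `2` = "B"))

  # a pair linked by two fine types counts twice
  multi <- globalNetwork(c("A", "A"), c("B", "B"),
                         type = c("interaction", "catalyze"))
  idx3 <- buildDegreeIndex(multi)
  expect_equal(idx3@buckets, list(`2` = c("A", "B")))
})

test_that("singleton buckets force the identity sample", {
  # degrees: A=1, B=2, C=3, D=1, E=1 -> B and C sit in singleton buckets
  net <- globalNetwork(c("A", "B", "C", "C"), c("B", "C", "D", "E"))
  idx <- buildDegreeIndex(net)
  expect_equal(idx@buckets[["2"]], "B")
  expect_equal(idx@buckets[["3"]], "C")
  got <- sampleMatchedNodeSet(c("B", "C"), idx, net, seed = 4)
  expect_setequal(as.character(got), c("B", "C"))
  expect_equal(attr(got, "fallbacks"), 0L)
})

test_that("a bucket-sized query returns the whole bucket", {
  tri <- globalNetwork(c("A", "B", "C"), c("B", "C", "A"))
  idx <- buildDegreeIndex(tri)
  got <- sampleMatchedNodeSet(c("A", "B", "C"), idx, tri, seed = 1)
  expect_setequal(as.character(got), c("A", "B", "C"))
})

test_that("bucket members are drawn uniformly", {
  # one bucket of 12 degree-1 nodes (6 disjoint pairs); query 3 of them
  a <- sprintf("u%02d", 1:6); b <- sprintf("v%02d", 1:6)
  net <- globalNetwork(a, b)
  idx <- buildDegreeIndex(net)
  gs <- c("u01", "u02", "u03")
  nDraw <- 1000
  set.seed(10)
  hits <- table(unlist(lapply(seq_len(nDraw), function(i)
    as.character(sampleMatchedNodeSet(gs, idx, net)))))
  expect_setequal(names(hits), c(a, b))
  pSel <- 3 / 12
  se <- sqrt(pSel * (1 - pSel) / nDraw)
  expect_true(all(abs(hits / nDraw - pSel) < 3 * se))
})

test_that("null counts are deterministic, sized, and leave the network intact", {
  w <- smallWorld()
  before <- edgeTable(w@net)
  gs <- w@modules[[1]]
  ns1 <- generateNullCounts(w@net, gs, n = 50, seed = 123)
  ns2 <- generateNullCounts(w@net, gs, n = 50, seed = 123)
  expect_identical(nullCounts(ns1), nullCounts(ns2))
  expect_length(nullCounts(ns1), 50L)
  expect_true(all(nullCounts(ns1) >= 0))
  expect_identical(edgeTable(w@net), before)
  ns3 <- generateNullCounts(w@net, gs, n = 50, seed = 124)
  expect_false(identical(nullCounts(ns1), nullCounts(ns3)))
})

test_that("degenerate geometries give the forced counts", {
  # the only edges touch the hub; leaf-only sets are always edgeless
  star <- starNet(8)
  leaves <- grep("^L", networkNodes(star), value = TRUE)
  ns <- generateNullCounts(star, leaves[1:4], n = 30, seed = 5)
  expect_true(all(nullCounts(ns) == 0L))

  # complete graph K6: every triple induces a triangle
  pairs <- t(combn(LETTERS[1:6], 2))
  k6 <- globalNetwork(pairs[, 1], pairs[, 2])
  ns2 <- generateNullCounts(k6, c("A", "B", "C"), n = 30, seed = 5)
  expect_true(all(nullCounts(ns2) == 3L))
})

test_that("sampled sets match the query degree multiset with no fallbacks", {
  w <- smallWorld()
  idx <- buildDegreeIndex(w@net)
  set.seed(77)
  gs <- sample(names(idx@degrees)[idx@degrees >= 1], 30)
  for (i in 1:25) {
    got <- sampleMatchedNodeSet(gs, idx, w@net)
    expect_equal(attr(got, "fallbacks"), 0L)
    expect_false(anyDuplicated(got) > 0)
    expect_equal(sort(unname(idx@degrees[as.character(got)])),
                 sort(unname(idx@degrees[gs])))
  }
  ns <- generateNullCounts(w@net, gs, n = 200, seed = 42)
  expect_equal(ns@policy$fallbacks, 0L)
})

test_that("empirical null mean matches exhaustive enumeration on a tiny world", {
  net <- tinyNet()
  members <- c("a", "b")   # both degree 2, bucket {a,b,e,g}
  exact <- enumNullDistribution(net, members)
  ns <- generateNullCounts(net, members, n = 2000, seed = 31)
  se <- sd(exact) / sqrt(2000)
  expect_lt(abs(mean(nullCounts(ns)) - mean(exact)), 3 * se + 1e-12)
})

test_that("degree-0 query nodes are rejected with a clear message", {
  net <- globalNetwork("A", "B", extraNodes = "Z")
  idx <- buildDegreeIndex(net)
  expect_error(sampleMatchedNodeSet(c("A", "Z"), idx, net), "degree 0")
})

test_that("null samples serialize to JSON for audit", {
  ns <- generateNullCounts(toyNet(), c("A", "B"), n = 10, seed = 2)
  f <- withr::local_tempfile()
  writeNullSample(ns, f)
  js <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(js$counts, nullCounts(ns))
  expect_equal(js$seed, 2L)
  expect_equal(js$policy$method, "degree_matched_node_permutation")
})
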