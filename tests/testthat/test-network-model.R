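test_that("generic TSV reading drops self-loops and canonicalizes", {
  f <- withr::local_tempfile(lines = c("A\tB\tinteraction",
                                       "B\tC\tcatalyze",
                                       "A\tA\tinteraction"))
  expect_message(net <- readEdgeList(f), "1 self-loop")
  expect_equal(length(networkNodes(net)), 3L)
  expect_equal(linkCount(net), 2L)
  expect_equal(net@metadata$droppedSelfLoops, 1L)
})

test_that("STRING dialect maps columns and fine type", {
  f <- withr::local_tempfile(lines = c("protein1 protein2 combined_score",
                                       "P1 P2 700"))
  net <- readEdgeList(f, dialect = "string_links")
  tab <- edgeTable(net)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$score, 700L)
  expect_equal(tab$type, "interaction")
})

test_that("duplicate (pair, type) rows collapse keeping the max score", {
  f <- withr::local_tempfile(lines = c("A\tB\tinteraction\t300",
                                       "B\tA\tinteraction\t500"))
  net <- readEdgeList(f)
  expect_equal(linkCount(net), 1L)
  expect_equal(edgeTable(net)$score, 500L)
})

test_that("A-B and B-A rows of one type yield one edge; different types two", {
  f <- withr::local_tempfile(lines = c("A\tB\tinteraction",
                                       "B\tA\tinteraction",
                                       "B\tA\tcatalyze"))
  net <- readEdgeList(f)
  expect_equal(linkCount(net), 2L)
  expect_equal(sort(edgeTable(net)$type), c("catalyze", "interaction"))
})

test_that("malformed and empty files raise named errors", {
  bad <- withr::local_tempfile(lines = c("A\tB\tinteraction", "A\tB"))
  expect_error(readEdgeList(bad), "line 2")
  empty <- withr::local_tempfile(lines = c("# only a comment"))
  expect_error(readEdgeList(empty), "no data rows")
})

test_that("score thresholding filters edges, keeps nodes, errors unscored", {
  net <- globalNetwork(c("A", "B", "C"), c("B", "C", "D"),
                       score = c(150L, 400L, 900L))
  expect_equal(linkCount(applyScoreThreshold(net, 400)), 2L)
  expect_equal(linkCount(applyScoreThreshold(net, 0)), 3L)
  hi <- applyScoreThreshold(net, 1001)
  expect_equal(linkCount(hi), 0L)
  expect_equal(networkNodes(hi), networkNodes(net))
  unscored <- globalNetwork("A", "B")
  expect_error(applyScoreThreshold(unscored, 400), "unscored")
  expect_identical(applyScoreThreshold(unscored, 0), unscored)
})

test_that("thresholding is monotone in the threshold", {
  set.seed(42)
  n <- 40
  net <- globalNetwork(sample(LETTERS, n, TRUE), sample(letters, n, TRUE),
                       sample(c("interaction", "catalyze"), n, TRUE),
                       score = sample(0:1000, n, TRUE))
  key <- function(x) with(edgeTable(x), paste(a, b, type))
  thresholds <- c(0, 150, 400, 700, 900)
  for (i in seq_len(length(thresholds) - 1)) {
    lo <- applyScoreThreshold(net, thresholds[i])
    hi <- applyScoreThreshold(net, thresholds[i + 1])
    expect_true(all(key(hi) %in% key(lo)))
  }
})

test_that("gene-set mapping resolves, reports unmapped, deduplicates", {
  net <- globalNetwork(c("P1", "P2"), c("P2", "P3"))
  mapping <- c(g1 = "P1", g2 = "P2")
  gs <- geneSet(c("g1", "g2"), net, mapping)
  expect_setequal(mappedNodes(gs), c("P1", "P2"))
  expect_length(unmappedIds(gs), 0L)

  gs2 <- geneSet(c("g1", "gX"), net, mapping)
  expect_equal(mappedNodes(gs2), "P1")
  expect_equal(unmappedIds(gs2), "gX")

  gs3 <- geneSet(c("g1", "g1"), net, mapping)
  expect_equal(mappedNodes(gs3), "P1")

  expect_error(geneSet(c("zz"), net, mapping), "namespace")
})

test_that("gene-set files accept plain lists and single GMT rows", {
  net <- globalNetwork(c("P1", "P2"), c("P2", "P3"))
  plain <- withr::local_tempfile(lines = c("P1", "P3", "# note", "PX"))
  gs <- readGeneSet(plain, net)
  expect_setequal(mappedNodes(gs), c("P1", "P3"))
  expect_equal(unmappedIds(gs), "PX")
  gmtrow <- withr::local_tempfile(lines = "myset\tdesc\tP1\tP2")
  expect_setequal(mappedNodes(readGeneSet(gmtrow, net)), c("P1", "P2"))
})

test_that("GMT read/write round-trips and rejects short rows", {
  f <- withr::local_tempfile(lines = "apoptosis\tdesc\tA\tB")
  expect_equal(readGmt(f), list(apoptosis = c("A", "B")))
  short <- withr::local_tempfile(lines = "name-only\tdesc")
  expect_error(readGmt(short), "fewer than 3")

  sets <- list(s1 = c("A", "B"), s2 = c("C"), s3 = c("D", "E", "F"))
  out <- withr::local_tempfile()
  writeGmt(sets, out)
  expect_equal(readGmt(out), sets)
})

test_that("edge-list write/read round-trip preserves edges and scores", {
  set.seed(1)
  n <- 30
  net <- globalNetwork(sample(LETTERS[1:10], n, TRUE),
                       sample(LETTERS[11:20], n, TRUE),
                       sample(c("interaction", "coexpression"), n, TRUE),
                       score = sample(100:900, n, TRUE))
  f <- withr::local_tempfile()
  writeEdgeList(net, f)
  back <- readEdgeList(f)
  ord <- function(x) { t <- edgeTable(x); t[order(t$a, t$b, t$type), ] }
  expect_equal(ord(back), ord(net), ignore_attr = TRUE)
  expect_equal(networkNodes(back), networkNodes(net))
})

test_that("publication counts and ID mappings parse and validate", {
  f <- withr::local_tempfile(lines = c("P1\t120", "P2\t0"))
  expect_equal(readPubCounts(f), c(P1 = 120L, P2 = 0L))
  bad <- withr::local_tempfile(lines = "P1\t-3")
  expect_error(readPubCounts(bad), "non-negative")
  m <- withr::local_tempfile(lines = c("g1\tP1", "g2\tP2"))
  expect_equal(readIdMapping(m), c(g1 = "P1", g2 = "P2"))
})
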