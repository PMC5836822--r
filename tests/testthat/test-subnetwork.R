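test_that("induced subnetwork keeps exactly the intra-set edges", {
  net <- toyNet()  # AB BC CD DA AC
  sub <- extractSubnetwork(net, c("A", "B", "C"))
  expect_equal(linkCount(sub), 3L)  # AB, BC, AC
  expect_setequal(networkNodes(sub), c("A", "B", "C"))

  # the whole node set reproduces the network
  all <- extractSubnetwork(net, networkNodes(net))
  expect_equal(linkCount(all), linkCount(net))
  ord <- function(x) { t <- edgeTable(x); t[order(t$a, t$b, t$type), ] }
  expect_equal(ord(all)[c("a", "b", "type")], ord(net)[c("a", "b", "type")],
               ignore_attr = TRUE)

  # unconnected pair
  expect_equal(linkCount(extractSubnetwork(net, c("A", "C"))), 1L)
  expect_equal(linkCount(extractSubnetwork(net, c("B", "D"))), 0L)
  expect_error(extractSubnetwork(net, character(0)), "empty")
})

test_that("induced link counts agree with igraph on random multigraphs", {
  skip_if_not_installed("igraph")
  set.seed(3)
  for (rep in 1:5) {
    n <- 60
    a <- sample(sprintf("n%02d", 1:25), n, TRUE)
    b <- sample(sprintf("n%02d", 1:25), n, TRUE)
    keep <- a != b
    net <- globalNetwork(a[keep], b[keep],
                         sample(c("interaction", "catalyze"), sum(keep), TRUE))
    g <- igraph::graph_from_data_frame(edgeTable(net)[, c("a", "b")],
                                       directed = FALSE,
                                       vertices = networkNodes(net))
    members <- sample(networkNodes(net), 10)
    expect_equal(linkCount(extractSubnetwork(net, members)),
                 igraph::ecount(igraph::induced_subgraph(g, members)))
  }
})

test_that("type filtering restricts edges and partitions the total", {
  net <- typedNet()
  sub <- extractSubnetwork(net, networkNodes(net))
  expect_equal(linkCount(filterByType(sub, "catalysis")), 1L)
  expect_identical(filterByType(sub, "all_types"), sub)
  expect_error(filterByType(filterByType(sub, "catalysis"), "coexpression"),
               "already filtered")

  # partition accounting on a generated network with "other" types present
  w <- smallWorld()
  s <- extractSubnetwork(w@net, networkNodes(w@net))
  perGroup <- vapply(coarseGroupLevels(),
                     function(g) linkCount(filterByType(s, g)), integer(1))
  expect_equal(sum(perGroup), linkCount(s))
  expect_true(sum(perGroup[setdiff(coarseGroupLevels(), "other")]) <=
                linkCount(s))
})

test_that("specificity rate is the in-set share of a node's global links", {
  # hub X with 14 links, 13 partners inside the analysed set
  partners <- sprintf("P%02d", 1:14)
  net <- globalNetwork(rep("X", 14), partners)
  sub <- extractSubnetwork(net, c("X", partners[1:13]))
  expect_equal(round(specificityRate(sub, net, "X"), 3), 0.929)

  subAll <- extractSubnetwork(net, c("X", partners))
  expect_equal(specificityRate(subAll, net, "X"), 1.0)
  leafOnly <- extractSubnetwork(net, partners)  # hub X excluded
  expect_equal(specificityRate(leafOnly, net, "P14"), 0.0)
  # isolated-in-global under the active filter -> error, not 0
  lone <- globalNetwork(c("X", "Y"), c("Z", "W"))
  s2 <- extractSubnetwork(lone, c("X", "Y"))
  expect_error(filterByType(s2, "catalysis") |>
                 specificityRate(lone, "X"), "undefined")
})

test_that("node ranking is descending with lexicographic tie-break", {
  net <- starNet(4)
  sub <- extractSubnetwork(net, networkNodes(net))
  r <- rankNodes(sub, by = "degree")
  expect_equal(r$node[1], "H")
  expect_equal(r$value[1], 4)
  expect_equal(r$node[-1], sort(r$node[-1]))  # tied leaves in lexicographic order

  # ranking by specificity rate agrees with direct recomputation
  w <- smallWorld()
  members <- w@modules[[1]]
  sub2 <- extractSubnetwork(w@net, members)
  r2 <- rankNodes(sub2, by = "specificity_rate", net = w@net)
  direct <- vapply(r2$node, function(nd) specificityRate(sub2, w@net, nd),
                   numeric(1))
  expect_equal(r2$value, unname(direct))
  expect_true(all(diff(r2$value) <= 0))
})

test_that("link count is invariant under node relabeling", {
  net <- toyNet()
  relabel <- globalNetwork(c("W1", "W2", "W3", "W4", "W1"),
                           c("W2", "W3", "W4", "W1", "W3"))
  expect_equal(linkCount(extractSubnetwork(net, c("A", "B", "C"))),
               linkCount(extractSubnetwork(relabel, c("W1", "W2", "W3"))))
})

test_that("subnetwork export writes TSV plus JSON summary", {
  sub <- extractSubnetwork(toyNet(), c("A", "B", "C"))
  prefix <- withr::local_tempfile()
  writeSubnetwork(sub, prefix)
  expect_equal(linkCount(readEdgeList(paste0(prefix, ".tsv"))), 3L)
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$link_count, 3L)
  expect_equal(js$nodes, 3L)
})
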