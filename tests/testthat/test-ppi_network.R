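graph_from_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  build_graph(edge_list(m[, 1], m[, 2]))
}

test_that("build_graph yields a simple undirected edge-defined graph", {
  g <- graph_from_pairs("a", "b", "b", "c")
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)

  empty <- build_graph(data.frame(a = character(0), b = character(0)))
  expect_equal(igraph::vcount(empty), 0L)

  # reader dirt (reversed duplicates, self loops) cannot change the graph
  dirty <- edge_list(c("a", "b", "a"), c("b", "a", "a"))
  clean <- edge_list("a", "b")
  expect_identical(igraph::as_edgelist(build_graph(dirty)),
                   igraph::as_edgelist(build_graph(clean)))
})

test_that("largest_component keeps the biggest component, ties lexicographic", {
  g <- graph_from_pairs("a", "b", "b", "c", "x", "y")
  lc <- largest_component(g)
  expect_setequal(igraph::V(lc)$name, c("a", "b", "c"))

  conn <- graph_from_pairs("a", "b", "b", "c")
  expect_equal(igraph::vcount(largest_component(conn)), 3L)

  tied <- graph_from_pairs("c", "d", "a", "b")
  expect_setequal(igraph::V(largest_component(tied))$name, c("a", "b"))

  expect_error(largest_component(build_graph(
    data.frame(a = character(0), b = character(0)))), "empty")
})

test_that("degree and average neighbor degree on canonical graphs", {
  star <- graph_from_pairs("hub", "l1", "hub", "l2", "hub", "l3")
  f <- node_features(star)
  expect_equal(f$degree[f$node == "hub"], 3L)
  expect_true(all(f$degree[f$node != "hub"] == 1L))
  expect_equal(f$avg_neighbor_degree[f$node == "hub"], 1)
  expect_true(all(f$avg_neighbor_degree[f$node != "hub"] == 3))

  tri <- graph_from_pairs("a", "b", "b", "c", "a", "c")
  f <- node_features(tri)
  expect_true(all(f$degree == 2L))
  expect_true(all(f$avg_neighbor_degree == 2))

  # handshake lemma on random graphs; d-regular ring has knn = d everywhere
  set.seed(131)
  for (rep in 1:10) {
    e <- random_connected_edges(8L, 0.5)
    g <- build_graph(e)
    expect_equal(sum(igraph::degree(g)), 2L * nrow(e))
  }
  ring <- build_graph(edge_list(paste0("r", 1:6),
                                paste0("r", c(2:6, 1))))
  f <- node_features(ring)
  expect_true(all(f$avg_neighbor_degree == 2))
})

test_that("betweenness matches hand values on path and star", {
  path <- graph_from_pairs("a", "b", "b", "c")
  f <- node_features(path)
  expect_equal(f$betweenness[f$node == "b"], 1)
  expect_true(all(f$betweenness[f$node != "b"] == 0))

  star <- graph_from_pairs("hub", "l1", "hub", "l2", "hub", "l3")
  f <- node_features(star)
  expect_equal(f$betweenness[f$node == "hub"], 3)   # three leaf pairs

  # degree-1 nodes of a tree sit on no interior path
  tree <- graph_from_pairs("r", "a", "r", "b", "a", "c", "a", "d")
  f <- node_features(tree)
  leaves <- c("b", "c", "d")
  expect_true(all(f$betweenness[f$node %in% leaves] == 0))
})

test_that("betweenness agrees with exhaustive path enumeration on small graphs", {
  set.seed(141)
  for (rep in 1:25) {
    e <- random_connected_edges(8L, 0.4)
    g <- build_graph(e)
    f <- node_features(g)
    oracle <- oracle_betweenness(e, sort(f$node))
    expect_equal(f$betweenness[order(f$node)], unname(oracle),
                 tolerance = 1e-9)
    # total betweenness equals the oracle's interior-weight total
    expect_equal(sum(f$betweenness), sum(oracle), tolerance = 1e-9)
  }
})

test_that("features are invariant under node relabeling", {
  set.seed(151)
  e <- random_connected_edges(8L, 0.5)
  f1 <- node_features(build_graph(e))
  perm <- setNames(paste0("z", sample(99, length(unique(c(e$a, e$b))))),
                   unique(c(e$a, e$b)))
  e2 <- edge_list(unname(perm[e$a]), unname(perm[e$b]))
  f2 <- node_features(build_graph(e2))
  f1$node <- unname(perm[f1$node])
  f1 <- f1[order(f1$node), ]; f2 <- f2[order(f2$node), ]
  expect_equal(f1$degree, f2$degree)
  expect_equal(f1$betweenness, f2$betweenness)
  expect_equal(f1$avg_neighbor_degree, f2$avg_neighbor_degree)
})

test_that("mean neighbor degree exceeds mean degree on random graphs", {
  # friendship-paradox direction, on average over seeds
  set.seed(161)
  diffs <- vapply(1:15, function(i) {
    g <- igraph::sample_gnp(40, 0.12)
    comp <- igraph::components(g)
    g <- igraph::induced_subgraph(g, comp$membership ==
                                    which.max(comp$csize))
    igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g)))
    f <- node_features(g)
    mean(f$avg_neighbor_degree) - mean(f$degree)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("group summaries aggregate features per chromosome", {
  gm <- map_from_sizes(c(chrA = 2L, chrB = 1L))
  f <- data.frame(node = c(gm$protein_id, "orphan"),
                  degree = c(4L, 4L, 2L, 7L),
                  betweenness = c(1, 1, 0, 3),
                  avg_neighbor_degree = c(3, 3, 5, 2),
                  stringsAsFactors = FALSE)
  gs <- group_summary(f, gm)
  a <- gs[gs$group == "chrA", ]
  expect_equal(a$n_nodes, 2L)
  expect_equal(a$mean_degree, 4)
  expect_equal(a$se_degree, 0)          # identical values
  b <- gs[gs$group == "chrB", ]
  expect_equal(b$se_degree, 0)          # single node: flagged, se 0
  expect_false(b$se_defined)
  expect_true("unmapped" %in% gs$group)
  expect_equal(gs$mean_degree[gs$group == "unmapped"], 7)
})
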