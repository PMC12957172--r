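test_that("network construction validates and keeps isolated nodes", {
  nodes <- c("a", "b", "c", "d", "e")
  edges <- data.frame(code_i = c("a", "a", "b", "c"),
                      code_j = c("b", "c", "c", "d"),
                      weight = c(0.5, 0.4, 0.3, 0.2),
                      stringsAsFactors = FALSE)
  nw <- build_network(nodes, edges, "toy")
  # adjacency matches the hand-built matrix
  adj <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  adj["a", "b"] <- adj["b", "a"] <- 0.5
  adj["a", "c"] <- adj["c", "a"] <- 0.4
  adj["b", "c"] <- adj["c", "b"] <- 0.3
  adj["c", "d"] <- adj["d", "c"] <- 0.2
  got <- as.matrix(igraph::as_adjacency_matrix(nw$graph, attr = "weight"))
  expect_equal(got[nodes, nodes], adj)
  # isolated node retained
  expect_true("e" %in% nw$nodes)
  expect_equal(node_metrics(nw)$degree[nw$nodes == "e"], 0L)
  # empty edge list -> all isolated
  nw0 <- build_network(nodes, edges[0, ], "empty")
  expect_equal(sum(node_metrics(nw0)$degree), 0L)
  # validation errors
  expect_error(build_network(nodes, rbind(edges, edges[1, ])), "duplicate")
  expect_error(build_network(c("a", "b"),
                             data.frame(code_i = "a", code_j = "z",
                                        weight = 0.5)), "z")
  expect_error(build_network(nodes, transform(edges, weight = c(0.5, 0, 0.3, 0.2))),
               "weight")
  expect_error(build_network(nodes, data.frame(code_i = "a", code_j = "a",
                                               weight = 0.1)), "self-loop")
})

test_that("network summary reproduces printed-style metrics", {
  # 22 nodes / 82 edges and 20 nodes / 89 edges worked examples
  s1 <- summarize_network(make_simple_graph(22, 82))
  expect_equal(round(s1$density, 3), 0.355)
  expect_equal(round(s1$avg_degree, 3), 7.455)
  s2 <- summarize_network(make_simple_graph(20, 89))
  expect_equal(round(s2$density, 3), 0.468)
  expect_equal(round(s2$avg_degree, 3), 8.900)
  # complete graph density 1
  s3 <- summarize_network(make_simple_graph(5, 10))
  expect_equal(s3$density, 1)
  expect_error(summarize_network(build_network("a", data.frame(
    code_i = character(0), code_j = character(0), weight = numeric(0)))),
    "density undefined")
})

test_that("harmonic centrality uses inverse hop counts over n-1", {
  star <- build_network(
    c("hub", "l1", "l2", "l3", "l4"),
    data.frame(code_i = "hub", code_j = c("l1", "l2", "l3", "l4"),
               weight = 0.5), "star")
  hc <- harmonic_centrality(star)
  expect_equal(unname(hc["hub"]), 1)
  # leaves: 1 hop to hub, 2 hops to the other three leaves
  expect_equal(unname(hc["l1"]), (1 + 3 / 2) / 4)
  path <- build_network(c("a", "b", "c"),
                        data.frame(code_i = c("a", "b"),
                                   code_j = c("b", "c"), weight = 0.9), "p")
  expect_equal(unname(harmonic_centrality(path)["a"]), (1 + 1 / 2) / 2)
  # disconnected: isolated node scores 0, everything stays in [0,1]
  iso <- build_network(c("a", "b", "z"),
                       data.frame(code_i = "a", code_j = "b", weight = 0.4),
                       "iso")
  hz <- harmonic_centrality(iso)
  expect_equal(unname(hz["z"]), 0)
  for (s in 1:5) {
    hc <- harmonic_centrality(random_network(8, seed = s))
    expect_true(all(hc >= 0 & hc <= 1))
  }
})

test_that("PageRank matches dense power iteration and igraph", {
  # unweighted cycle: uniform scores by symmetry
  cyc <- build_network(letters[1:6], data.frame(
    code_i = letters[1:6], code_j = letters[c(2:6, 1)], weight = 1), "cyc")
  expect_equal(unname(pagerank_scores(cyc)), rep(1 / 6, 6), tolerance = 1e-9)
  for (s in 1:8) {
    nw <- random_network(7, p_edge = 0.35, seed = 40 + s)
    pr <- pagerank_scores(nw)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(pr, brute_pagerank(nw), tolerance = 1e-8)
    ig <- igraph::page_rank(nw$graph, damping = 0.85,
                            weights = igraph::E(nw$graph)$weight)$vector
    expect_equal(pr[nw$nodes], ig[nw$nodes], tolerance = 1e-6)
  }
  # node insertion order does not matter
  nw <- random_network(6, seed = 77)
  rev_nodes <- rev(nw$nodes)
  nw2 <- build_network(rev_nodes, nw$edges, nw$label)
  expect_equal(pagerank_scores(nw)[nw$nodes], pagerank_scores(nw2)[nw$nodes],
               tolerance = 1e-9)
})

test_that("hubs rank by PageRank with lexicographic ties", {
  nw <- random_network(9, seed = 5)
  hubs <- pagerank_hubs(nw, k = 4)
  pr <- pagerank_scores(nw)
  expect_equal(hubs$pagerank, unname(sort(pr, decreasing = TRUE)[1:4]))
  expect_equal(hubs$rank, 1:4)
  # perfect symmetry forces ties: lexicographic order decides
  cyc <- build_network(c("b", "a", "c"), data.frame(
    code_i = c("a", "b", "c"), code_j = c("b", "c", "a"), weight = 1), "c3")
  expect_equal(pagerank_hubs(cyc, k = 3)$code, c("a", "b", "c"))
})

test_that("degree identities hold on random graphs", {
  for (s in 1:5) {
    nw <- random_network(8, seed = 60 + s)
    nm <- node_metrics(nw)
    expect_equal(sum(nm$degree), 2L * nrow(nw$edges))
    expect_equal(sum(nm$weighted_degree), 2 * sum(nw$edges$weight))
    su <- summarize_network(nw)
    n <- su$n_nodes
    expect_equal(su$density, su$n_edges / (n * (n - 1) / 2))
    expect_equal(su$avg_degree, 2 * su$n_edges / n)
  }
})

test_that("system aggregates sum degrees per chapter", {
  nodes <- c("a", "b", "c", "d")
  edges <- data.frame(code_i = c("a", "a", "c"), code_j = c("b", "c", "d"),
                      weight = c(0.5, 0.25, 0.75), stringsAsFactors = FALSE)
  nw <- build_network(nodes, edges, "sys")
  catalog <- data.frame(condition_code = nodes,
                        label = nodes,
                        icd10_chapter = c("IX", "IX", "XI", "XI"),
                        is_index_disease = 0L, stringsAsFactors = FALSE)
  agg <- system_aggregates(nw, catalog)
  # hand summation: IX gets deg(a)+deg(b)=2+1, XI gets deg(c)+deg(d)=2+1
  expect_equal(agg$total_degree[agg$chapter == "IX"], 3)
  expect_equal(agg$total_weighted_degree[agg$chapter == "IX"],
               (0.5 + 0.25) + 0.5)
  expect_equal(agg$total_weighted_degree[agg$chapter == "XI"],
               (0.25 + 0.75) + 0.75)
  # single-chapter handshake: total = 2 * number of edges
  cat1 <- transform(catalog, icd10_chapter = "IX")
  expect_equal(system_aggregates(nw, cat1)$total_degree, 2 * nrow(edges))
  expect_error(system_aggregates(nw, catalog[1:3, ]), "d")
})
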