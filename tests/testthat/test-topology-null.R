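test_that("global_topology matches closed forms on canonical graphs", {
  k3 <- igraph::make_full_graph(3)
  t3 <- global_topology(k3)
  expect_equal(t3$clustering, 1)
  expect_equal(t3$path_length, 1)
  expect_equal(t3$diameter, 1)
  expect_equal(t3$density, 1)

  p3 <- igraph::make_graph(~ a - b - c)
  tp <- global_topology(p3)
  expect_equal(tp$path_length, 4 / 3)
  expect_equal(tp$diameter, 2)
  expect_equal(tp$clustering, 0)

  star <- igraph::make_star(5, mode = "undirected")
  ts <- global_topology(star)
  # degrees {4,1,1,1,1}: sqrt(population var)/mean = sqrt(1.44)/1.6
  expect_equal(ts$heterogeneity, 0.75)
  # centralization of a star is 1
  expect_equal(ts$centralization, 1)
  expect_equal(ts$average_neighbors, 2 * 4 / 5)

  expect_error(global_topology(igraph::make_empty_graph(0, directed = FALSE)),
               "at least 2")
})

test_that("path statistics cover connected pairs of disconnected graphs", {
  g <- igraph::make_full_graph(3) + igraph::make_full_graph(2)
  tt <- global_topology(g)
  expect_equal(tt$path_length, 1)  # all connected pairs at distance 1
  tl <- global_topology(g, paths = "largest_component")
  expect_equal(tl$diameter, 1)
})

test_that("er_null draws G(n,m) with exactly m edges and ER-level clustering", {
  null <- er_null(100, 300, reps = 200, seed = 7)
  expect_equal(null$density_r, 300 / choose(100, 2))  # fixed edge count
  p_er <- 300 / choose(100, 2)
  expect_lt(abs(null$clustering_r - p_er), 3 * null$clustering_r_se + 0.002)
  # determinism
  null2 <- er_null(100, 300, reps = 200, seed = 7)
  expect_identical(null, null2)
})

test_that("small_world composes the two null-normalized ratios", {
  expect_equal(small_world(5.29, 1, 1.78, 1), 5.29 / 1.78)
  expect_equal(small_world(0.3, 0.3, 2.2, 2.2), 1)
  expect_error(small_world(0.5, 0, 2, 1), "positive")
})

test_that("louvain recovers planted cliques and matches brute-force optimum", {
  g <- two_clique_bridge()
  part <- louvain_modules(g, seed = 5)
  expect_equal(length(unique(part$module)), 2)
  expect_equal(part$module[1:4], rep(part$module[1], 4))
  expect_equal(part$module[5:8], rep(part$module[5], 4))
  # the clique split is the global modularity optimum over all partitions
  bf <- brute_force_max_modularity(g)
  expect_equal(attr(part, "modularity"), bf$q, tolerance = 1e-12)
  expect_equal(as.integer(factor(part$module)),
               as.integer(factor(bf$partition)))
  # reported Q equals the hand modularity of the returned partition
  expect_equal(attr(part, "modularity"), modularity_q(g, part), tolerance = 1e-12)
})

test_that("louvain is deterministic under a seed and keeps components apart", {
  g <- igraph::sample_gnm(40, 60)
  p1 <- louvain_modules(g, seed = 3)
  p2 <- louvain_modules(g, seed = 3)
  expect_identical(p1, p2)

  g2 <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  part <- louvain_modules(g2, seed = 1)
  expect_equal(length(unique(part$module)), 2)

  single <- louvain_modules(igraph::make_full_graph(5), seed = 1)
  expect_equal(length(unique(single$module)), 1)
  expect_error(louvain_modules(igraph::make_empty_graph(3, directed = FALSE)),
               "at least one edge")
})

test_that("modularity_q implements the Newman definition", {
  g <- igraph::make_full_graph(4)
  expect_equal(modularity_q(g, rep(1, 4)), 0)
  # two disjoint K3s split by component: Q = 2 * (0.5 - 0.25) = 0.5
  g2 <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
  expect_equal(modularity_q(g2, c(1, 1, 1, 2, 2, 2)), 0.5)
  # agreement with igraph's implementation on random graphs and partitions
  set.seed(13)
  for (i in 1:10) {
    gr <- igraph::sample_gnm(30, 60)
    memb <- sample(1:4, 30, replace = TRUE)
    expect_equal(modularity_q(gr, memb),
                 igraph::modularity(gr, membership = memb), tolerance = 1e-12)
  }
  # random partition of an ER graph has Q ~ 0
  qs <- replicate(30, {
    gr <- igraph::sample_gnm(60, 180)
    modularity_q(gr, sample(1:3, 60, replace = TRUE))
  })
  expect_lt(abs(mean(qs)), 0.02)
  expect_error(modularity_q(igraph::make_full_graph(3), c(1, 1)), "length")
})

test_that("topology metrics are invariant under node relabeling", {
  set.seed(8)
  g <- igraph::sample_gnm(40, 80)
  igraph::V(g)$name <- paste0("v", 1:40)
  perm <- sample(40)
  g2 <- igraph::permute(g, perm)
  t1 <- global_topology(g)
  t2 <- global_topology(g2)
  expect_equal(t1, t2)
})

test_that("topology_summary assembles ratios and the small-world coefficient", {
  g <- two_clique_bridge()
  ts <- topology_summary(g, reps = 30, seed = 2)
  expect_equal(ts$c_ratio, ts$clustering / ts$clustering_r)
  expect_equal(ts$small_world, ts$c_ratio / ts$l_ratio)
  expect_equal(ts$n_nodes, 8)
  expect_equal(ts$n_edges, 13)
})
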