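test_that("within-module degree z-scores match hand computations", {
  # one module that is a star K1,4: within-degrees (4,1,1,1,1),
  # mean 1.6, population sd 1.2, hub Zi = (4-1.6)/1.2 = 2
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("n", 1:5)
  zi <- within_module_degree(star, rep(1, 5))
  expect_equal(zi$z_within[1], 2)
  expect_equal(zi$z_within[-1], rep(-0.5, 4))

  # K4 module: all within-degrees equal, all Zi = 0
  k4 <- igraph::make_full_graph(4)
  expect_equal(within_module_degree(k4, rep(1, 4))$z_within, rep(0, 4))

  # singleton module: sd = 0 gives Zi = 0
  g <- igraph::make_full_graph(3) + 1
  expect_equal(within_module_degree(g, c(1, 1, 1, 2))$z_within, rep(0, 4))
})

test_that("Zi values have per-module mean 0 and population sd 1", {
  set.seed(4)
  g <- igraph::sample_gnm(60, 150)
  part <- louvain_modules(g, seed = 1)
  zi <- within_module_degree(g, part)
  for (s in unique(zi$module)) {
    z <- zi$z_within[zi$module == s]
    k <- zi$k_within[zi$module == s]
    if (length(z) > 1 && sd(k) > 0) {
      expect_equal(mean(z), 0, tolerance = 1e-12)
      expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
    }
  }
})

test_that("participation coefficient matches closed forms", {
  # all edges inside own module
  k4 <- igraph::make_full_graph(4)
  expect_equal(participation_coefficient(k4, rep(1, 4))$p_among, rep(0, 4))

  # hub with degree 4 split evenly over 4 modules: Pi = 1 - 4/16 = 0.75
  star <- igraph::make_star(5, mode = "undirected")
  pi5 <- participation_coefficient(star, c(1, 1, 2, 3, 4))
  expect_equal(pi5$p_among[1], 0.75)

  # degree 2 split 1/1 over two modules
  p3 <- igraph::make_graph(~ a - b - c)
  pib <- participation_coefficient(p3, c(1, 1, 2))
  expect_equal(pib$p_among[pib$node_id == "b"], 0.5)

  # degree-0 nodes get 0
  g <- igraph::make_full_graph(3) + 1
  expect_equal(participation_coefficient(g, c(1, 1, 1, 2))$p_among[4], 0)
})

test_that("Pi respects its structural bounds and degree partition", {
  set.seed(12)
  g <- igraph::sample_gnm(50, 120)
  part <- louvain_modules(g, seed = 2)
  pc <- participation_coefficient(g, part)
  m_mod <- length(unique(part$module))
  expect_true(all(pc$p_among >= 0 & pc$p_among <= 1 - 1 / m_mod + 1e-12))
  # sum of per-module link counts equals total degree: implied by Pi <= 1
  # and checked directly via the within-degree complement
  zi <- within_module_degree(g, part)
  expect_true(all(zi$k_within <= pc$degree))
})

test_that("bridge endpoints of a two-clique graph carry the maximal Pi", {
  g <- two_clique_bridge()
  part <- louvain_modules(g, seed = 1)
  pc <- participation_coefficient(g, part)
  bridge <- pc$p_among[pc$node_id %in% c("n4", "n5")]
  others <- pc$p_among[!(pc$node_id %in% c("n4", "n5"))]
  expect_true(min(bridge) > max(others))
})

test_that("role classification partitions the Zi-Pi plane", {
  expect_equal(classify_role(0, 0), "peripheral")
  expect_equal(classify_role(1.0, 0.75), "connector")
  expect_equal(classify_role(3.0, 0.5), "module_hub")
  expect_equal(classify_role(3.0, 0.7), "network_hub")
  # boundary values belong to the low side (thresholds are strict >)
  expect_equal(classify_role(2.5, 0.62), "peripheral")
  set.seed(2)
  z <- rnorm(100, 1, 2)
  p <- runif(100)
  roles <- classify_role(z, p)
  expect_true(all(roles %in% c("peripheral", "connector", "module_hub",
                               "network_hub")))
  expect_equal(length(roles), 100)
})

test_that("node centralities match hand computations on small graphs", {
  p3 <- igraph::make_graph(~ a - b - c)
  nc <- node_centralities(p3)
  b_row <- nc[nc$node_id == "b", ]
  expect_equal(b_row$betweenness, 1)
  expect_equal(b_row$closeness, 1)  # 2 reachable / distance sum 2
  a_row <- nc[nc$node_id == "a", ]
  expect_equal(a_row$closeness, 2 / 3)
  expect_equal(a_row$avg_shortest_path, 1.5)

  k5 <- igraph::make_full_graph(5)
  expect_equal(node_centralities(k5)$betweenness, rep(0, 5))

  star <- igraph::make_star(5, mode = "undirected")
  ncs <- node_centralities(star)
  expect_equal(ncs$neighborhood_connectivity[-1], rep(4, 4))
  expect_equal(ncs$neighborhood_connectivity[1], 1)
})

test_that("category comparisons use rank-sum tests with caption-style stars", {
  set.seed(31)
  d <- tibble::tibble(
    category = rep(c("g", "s"), each = 10),
    metric = c(rnorm(10, 10), rnorm(10, 0))  # disjoint values
  )
  res <- compare_by_category(d, category = "category", metrics = "metric")
  expect_lt(res$p, 0.001)
  expect_equal(res$stars, "***")

  # identical distributions: no stars
  d2 <- tibble::tibble(category = rep(c("g", "s"), each = 8),
                       metric = rep(1:8, 2))
  res2 <- compare_by_category(d2, category = "category", metrics = "metric")
  expect_equal(res2$stars, "")

  expect_equal(significance_stars(c(0.02, 0.005, 5e-4, 0.2)),
               c("*", "**", "***", ""))

  # undersized categories are skipped with a warning
  d3 <- tibble::tibble(category = c(rep("a", 5), rep("b", 5), "c", "c"),
                       metric = rnorm(12))
  expect_warning(res3 <- compare_by_category(d3, category = "category",
                                             metrics = "metric"),
                 "skipping")
  expect_equal(nrow(res3), 1)
  expect_error(suppressWarnings(
    compare_by_category(tibble::tibble(category = c("a", "a", "b"),
                                       metric = 1:3),
                        category = "category", metrics = "metric")),
    "at least 2")
})

test_that("node_roles assembles a consistent per-node table", {
  g <- two_clique_bridge()
  part <- louvain_modules(g, seed = 1)
  nr <- node_roles(g, part)
  expect_equal(nrow(nr), 8)
  expect_true(all(c("z_within", "p_among", "role", "degree",
                    "betweenness", "closeness") %in% names(nr)))
  expect_true(all(nr$role == classify_role(nr$z_within, nr$p_among)))
})
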