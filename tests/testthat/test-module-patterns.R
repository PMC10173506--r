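test_that("major_modules applies the size rule and reports coverage", {
  part <- tibble::tibble(node_id = paste0("n", 1:100),
                         module = rep(1:5, c(40, 30, 20, 6, 4)))
  mm <- major_modules(part)
  expect_equal(mm$major, c(TRUE, TRUE, TRUE, TRUE, FALSE))  # cut = max(5, 2)
  expect_equal(attr(mm, "coverage"), 0.96)

  one <- major_modules(tibble::tibble(node_id = "a", module = 1), min_size = 1)
  expect_true(one$major)
  expect_equal(attr(one, "coverage"), 1)

  singles <- major_modules(tibble::tibble(node_id = paste0("n", 1:10),
                                          module = 1:10))
  expect_false(any(singles$major))
  expect_error(major_modules(tibble::tibble(node_id = character(),
                                            module = integer())), "empty")
})

test_that("feature_scale maps to [0,1] with degenerate handling", {
  expect_equal(feature_scale(c(2, 4, 6)), c(0, 0.5, 1))
  expect_warning(z <- feature_scale(c(5, 5, 5)), "constant")
  expect_equal(z, c(0, 0, 0))
  set.seed(6)
  x <- rnorm(50)
  sx <- feature_scale(x)
  expect_true(all(sx >= 0 & sx <= 1))
  expect_equal(range(sx), c(0, 1))
})

test_that("module_patterns averages feature-scaled member profiles", {
  m <- rbind(c(0, 5, 10), c(10, 5, 0), c(3, 6, 9))
  ft <- make_ft(m)
  part <- tibble::tibble(node_id = c("a01", "a02", "a03"),
                         module = c(1, 1, 2))
  pats <- module_patterns(ft, part)
  m1 <- pats$pattern[pats$module == 1]
  expect_true(all(pats$pattern >= 0 & pats$pattern <= 1))
  # single-member module pattern is that member's scaled profile
  m2 <- pats$pattern[pats$module == 2]
  rel3 <- m[3, ] / colSums(m)
  expect_equal(m2, unname(feature_scale(rel3)))

  # on abundance profiles, the anti-correlated pair scales to (0,.5,1) and
  # (1,.5,0): the averaged pattern is flat 0.5
  patsA <- module_patterns(ft, part, relative = FALSE)
  expect_equal(patsA$pattern[patsA$module == 1], rep(0.5, 3))

  # scale invariance: multiplying one member's abundances by a positive
  # constant leaves every pattern unchanged (feature scaling absorbs scale)
  m_scaled <- m
  m_scaled[1, ] <- m_scaled[1, ] * 7
  pats2 <- module_patterns(make_ft(m_scaled), part, relative = FALSE)
  expect_equal(pats2$pattern, patsA$pattern)

  expect_warning(module_patterns(ft, part, modules = c(1, 2, 9)), "dropped")
  expect_error(module_patterns(ft, tibble::tibble(node_id = "zz", module = 1)),
               "no module")
})

test_that("identical profiles give identical patterns", {
  m <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  ft <- make_ft(m)
  part <- tibble::tibble(node_id = c("a01", "a02"), module = c(1, 1))
  pats <- module_patterns(ft, part)
  expect_equal(pats$pattern, unname(feature_scale(m[1, ] / colSums(m))))
})

test_that("ward_cluster reproduces an exhaustive Ward oracle", {
  set.seed(17)
  for (rep in 1:5) {
    x <- matrix(rnorm(4 * 6), nrow = 4,
                dimnames = list(paste0("m", 1:4), paste0("s", 1:6)))
    hc <- ward_cluster(x)
    expect_equal(hc$height, ward_oracle_heights(x), tolerance = 1e-10)
    expect_true(all(diff(hc$height) >= -1e-12))  # monotone heights
  }
  # identical patterns merge first at height 0
  x2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  hc2 <- ward_cluster(x2)
  expect_equal(hc2$height[1], 0)
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
  expect_error(ward_cluster(x2[1, , drop = FALSE]), "at least 2")
})

test_that("dendrograms export as valid Newick with preserved tips", {
  set.seed(23)
  x <- matrix(rnorm(20), nrow = 5,
              dimnames = list(paste0("mod", 1:5), NULL))
  hc <- ward_cluster(x)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, tf)
  tree <- ape::read.tree(tf)
  expect_setequal(tree$tip.label, paste0("mod", 1:5))
})

test_that("module_env_correlation recovers monotone covariate links", {
  sid <- sprintf("s%02d", 1:30)
  elev <- seq(100, 300, length.out = 30)
  pats <- dplyr::bind_rows(
    tibble::tibble(module = 1, sample_id = sid,
                   pattern = feature_scale(elev)),
    tibble::tibble(module = 2, sample_id = sid,
                   pattern = feature_scale(rev(elev)))
  )
  md <- tibble::tibble(sample_id = sid, elevation = elev,
                       label = rep("x", 30))
  expect_warning(rho <- module_env_correlation(pats, md), "non-numeric")
  expect_equal(rho$rho[rho$module == "1"], 1)
  expect_equal(rho$rho[rho$module == "2"], -1)
})

test_that("intermodule edge densities follow the pair formulas", {
  g <- two_clique_bridge()
  part <- c(1, 1, 1, 1, 2, 2, 2, 2)
  im <- intermodule_edges(g, part)
  within1 <- im[im$module_a == 1 & im$module_b == 1, ]
  expect_equal(within1$n_edges, 6)
  expect_equal(within1$density, 1)  # clique
  expect_equal(within1$pct, 100)
  between <- im[im$module_a == 1 & im$module_b == 2, ]
  expect_equal(between$n_edges, 1)
  expect_equal(between$density, 1 / 16)
  expect_equal(between$pct, 6.3)  # 6.25 rounded half away from zero
  # conservation: per-pair counts sum to the edge total
  expect_equal(sum(im$n_edges), igraph::ecount(g))
})

test_that("env_subnetwork extracts factors plus direct neighbors", {
  # env node e1 linked to 3 ASVs; e2 isolated; one ASV-ASV edge among them
  edges <- tibble::tibble(
    source = c("e1", "e1", "e1", "x1"),
    target = c("x1", "x2", "x3", "x2"),
    rho = 0.8, p = 0, q = 0,
    env_env = FALSE
  )
  nodes <- tibble::tibble(id = c("e1", "e2", "x1", "x2", "x3", "x4"),
                          kind = c("env", "env", rep("asv", 4)),
                          category = c(NA, NA, "generalist", "generalist",
                                       "common", "specialist"))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  net <- structure(list(graph = g, nodes = nodes, edges = edges,
                        params = list()), class = "conetwork")
  expect_warning(sub <- env_subnetwork(net), "omitted")
  expect_setequal(igraph::V(sub$graph)$name, c("e1", "x1", "x2", "x3"))
  expect_equal(igraph::ecount(sub$graph), 3)  # ASV-ASV edge dropped
  sub2 <- suppressWarnings(env_subnetwork(net, include_asv_asv = TRUE))
  expect_equal(igraph::ecount(sub2$graph), 4)

  comp <- sub$composition
  gen <- comp[comp$category == "generalist", ]
  expect_equal(gen$n_linked, 2)
  expect_equal(gen$frac_of_factor_links, 2 / 3)
  expect_equal(gen$frac_of_category, 1)  # both network generalists linked

  no_env <- structure(list(graph = g, nodes = nodes[nodes$kind == "asv", ],
                           edges = edges, params = list()),
                      class = "conetwork")
  expect_error(env_subnetwork(no_env), "no environment nodes")
})
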