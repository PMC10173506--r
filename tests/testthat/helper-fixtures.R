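# Shared fixtures, built in code.

# Wide feature-table tibble from a count matrix.
make_ft <- function(m, asv_ids = NULL, sample_ids = NULL) {
  if (is.null(asv_ids)) asv_ids <- sprintf("a%02d", seq_len(nrow(m)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%02d", seq_len(ncol(m)))
  rownames(m) <- asv_ids
  colnames(m) <- sample_ids
  out <- tibble::as_tibble(m, rownames = "asv_id")
  out
}

# Two K4 cliques joined by a single bridge edge (8 nodes).
two_clique_bridge <- function() {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(4, 5))
  igraph::V(g)$name <- paste0("n", 1:8)
  g
}

# Brute-force maximum-modularity partition by enumerating all set
# partitions of the nodes (feasible for <= 8 nodes).
brute_force_max_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  parts <- set_partitions(n)
  qs <- vapply(parts, function(p) modularity_q(g, p), numeric(1))
  list(partition = parts[[which.max(qs)]], q = max(qs))
}

# All set partitions of n elements as membership vectors (restricted
# growth strings).
set_partitions <- function(n) {
  out <- list()
  rec <- function(i, memb, k) {
    if (i > n) {
      out[[length(out) + 1]] <<- memb
      return(invisible())
    }
    for (b in seq_len(k + 1)) {
      memb[i] <- b
      rec(i + 1, memb, max(k, b))
    }
  }
  rec(1, integer(n), 0)
  out
}

# Independent step-up BH oracle (literal definition).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  ps <- p[o]
  # q_(i) = min_{j >= i} m * p_(j) / j, capped at 1
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, m * ps[i:m] / seq(i, m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Midrank + explicit Pearson formula: independent oracle for Spearman rho.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Greedy Ward agglomeration using the closed-form inter-cluster distance
# sqrt(2 |A||B| / (|A|+|B|)) * ||centroid_A - centroid_B|| (the ward.D2
# criterion), independent of hclust's Lance-Williams recursion.
ward_oracle_heights <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        a <- clusters[[i]]; b <- clusters[[j]]
        ca <- colMeans(x[a, , drop = FALSE])
        cb <- colMeans(x[b, , drop = FALSE])
        d <- sqrt(2 * length(a) * length(b) / (length(a) + length(b))) *
          sqrt(sum((ca - cb)^2))
        if (d < best_d) {
          best_d <- d
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}

# Small pre-generated community reused across test files (generated once
# per test run; deterministic).
sim_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_community(scenario_config(), seed = 42)
    }
    cache
  }
})
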