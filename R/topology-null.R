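# Whole-network topology, Erdos-Renyi nulls, small-world coefficient,
# Louvain modularity.

#' Observed global topology of a network
#'
#' Computes the NetworkAnalyzer-style whole-graph statistics: density
#' `2m/(n(n-1))`, mean degree, diameter and characteristic path length over
#' connected pairs (or the largest component via `paths`), average local
#' clustering (nodes of degree < 2 contribute 0), degree heterogeneity
#' `sqrt(var(k))/mean(k)` (population variance), and degree centralization
#' `(n/(n-2)) * (max(k)/(n-1) - density)`.
#'
#' @param g An igraph graph (simple, undirected, at least 2 nodes).
#' @param paths `"connected_pairs"` (default): path statistics averaged over
#'   reachable pairs of the possibly disconnected graph; or
#'   `"largest_component"`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `diameter`,
#'   `average_neighbors`, `density`, `heterogeneity`, `centralization`,
#'   `clustering`, `path_length`.
#' @export
global_topology <- function(g, paths = c("connected_pairs", "largest_component")) {
  paths <- match.arg(paths)
  n <- igraph::vcount(g)
  if (n < 2) abort("global topology needs at least 2 nodes")
  if (igraph::any_multiple(g) || any(igraph::which_loop(g))) {
    abort("graph must be simple (no loops or multi-edges)")
  }
  m <- igraph::ecount(g)
  k <- igraph::degree(g)
  density <- 2 * m / (n * (n - 1))
  gp <- g
  if (paths == "largest_component") {
    comp <- igraph::components(gp)
    gp <- igraph::induced_subgraph(gp, which(comp$membership == which.max(comp$csize)))
  }
  local_c <- igraph::transitivity(g, type = "local", isolates = "zero")
  local_c[is.nan(local_c)] <- 0
  tibble(
    n_nodes = n,
    n_edges = m,
    diameter = if (m > 0) igraph::diameter(gp, unconnected = TRUE) else NA_real_,
    average_neighbors = 2 * m / n,
    density = density,
    heterogeneity = if (mean(k) > 0) pop_sd(k) / mean(k) else NA_real_,
    centralization = if (n > 2) (n / (n - 2)) * (max(k) / (n - 1) - density) else NA_real_,
    clustering = mean(local_c),
    path_length = if (m > 0) igraph::mean_distance(gp, unconnected = TRUE) else NA_real_
  )
}

#' Erdos-Renyi G(n, m) null expectations
#'
#' Draws `reps` uniform random graphs with exactly `n` nodes and `m` edges,
#' computes the global topology of each (plus Louvain modularity), and
#' returns per-metric means and standard errors. This is the null model for
#' ratio-normalized topology: same number of nodes and links, random
#' wiring.
#'
#' @param n,m Node and edge counts (`m <= n(n-1)/2`).
#' @param reps Number of replicates (default 100).
#' @param seed Integer seed; same seed, identical means.
#' @return One-row tibble with `clustering_r`, `path_length_r`,
#'   `heterogeneity_r`, `centralization_r`, `modularity_r`, `density_r` and
#'   matching `_se` columns.
#' @export
er_null <- function(n, m, reps = 100, seed = 1) {
  stopifnot(m <= n * (n - 1) / 2, reps >= 1)
  with_seed_(seed, {
    stats_tbl <- purrr::map_dfr(seq_len(reps), function(i) {
      gr <- igraph::sample_gnm(n, m)
      tp <- global_topology(gr)
      part <- igraph::membership(igraph::cluster_louvain(gr))
      tp$modularity <- modularity_q(gr, as.integer(part))
      tp
    })
    tibble(
      clustering_r = mean(stats_tbl$clustering),
      path_length_r = mean(stats_tbl$path_length),
      heterogeneity_r = mean(stats_tbl$heterogeneity),
      centralization_r = mean(stats_tbl$centralization),
      modularity_r = mean(stats_tbl$modularity),
      density_r = mean(stats_tbl$density),
      clustering_r_se = stats::sd(stats_tbl$clustering) / sqrt(reps),
      path_length_r_se = stats::sd(stats_tbl$path_length) / sqrt(reps),
      heterogeneity_r_se = stats::sd(stats_tbl$heterogeneity) / sqrt(reps),
      centralization_r_se = stats::sd(stats_tbl$centralization) / sqrt(reps),
      modularity_r_se = stats::sd(stats_tbl$modularity) / sqrt(reps)
    )
  })
}

#' Small-world coefficient
#'
#' `SW = (C / C_R) / (L / L_R)`: observed clustering and characteristic
#' path length, each normalized by the Erdos-Renyi null mean. SW > 1
#' indicates small-world organization.
#'
#' @param clustering,clustering_r Observed and null mean clustering.
#' @param path_length,path_length_r Observed and null mean path length.
#' @return The small-world coefficient (scalar).
#' @export
small_world <- function(clustering, clustering_r, path_length, path_length_r) {
  vals <- c(clustering, clustering_r, path_length, path_length_r)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("small_world needs four positive finite inputs")
  }
  (clustering / clustering_r) / (path_length / path_length_r)
}

#' Louvain community detection (deterministic under a seed)
#'
#' Wraps \code{igraph::cluster_louvain} under a fixed RNG seed so repeated
#' calls give identical partitions; also reports the achieved Newman
#' modularity.
#'
#' @param g igraph graph with at least one edge.
#' @param seed Integer seed.
#' @param resolution Resolution parameter (default 1 = plain modularity).
#' @return Tibble (`node_id`, `module`) with attributes `modularity` (Q of
#'   the returned partition, recomputed with [modularity_q()]) and
#'   `n_modules`.
#' @export
louvain_modules <- function(g, seed = 1, resolution = 1) {
  if (igraph::ecount(g) < 1) abort("community detection needs at least one edge")
  memb <- with_seed_(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  out <- tibble(node_id = ids, module = as.integer(memb))
  attr(out, "modularity") <- modularity_q(g, out$module)
  attr(out, "n_modules") <- length(unique(out$module))
  out
}

#' Newman modularity of a partition
#'
#' `Q = sum_s (e_s / m - (d_s / 2m)^2)` where `e_s` is the number of edges
#' inside module s and `d_s` the summed degree of its members. Implemented
#' directly from the definition (independent of igraph's modularity code).
#'
#' @param g igraph graph.
#' @param partition Module labels: either a vector aligned with the graph's
#'   vertices or a tibble (`node_id`, `module`).
#' @return Q, a scalar in `[-0.5, 1)`.
#' @export
modularity_q <- function(g, partition) {
  memb <- partition_vector(g, partition)
  m <- igraph::ecount(g)
  if (m == 0) abort("modularity is undefined for an edgeless graph")
  el <- igraph::as_edgelist(g, names = FALSE)
  same <- memb[el[, 1]] == memb[el[, 2]]
  k <- igraph::degree(g)
  e_s <- tapply(rep(1, sum(same)), memb[el[same, 1]], sum)
  d_s <- tapply(k, memb, sum)
  e_by_mod <- rep(0, length(d_s))
  names(e_by_mod) <- names(d_s)
  if (length(e_s) > 0) e_by_mod[names(e_s)] <- e_s
  sum(e_by_mod / m - (d_s / (2 * m))^2)
}

# Normalize a partition argument to an integer vector over g's vertices.
partition_vector <- function(g, partition) {
  n <- igraph::vcount(g)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.data.frame(partition)) {
    if (!all(ids %in% partition$node_id)) {
      missing <- setdiff(ids, partition$node_id)
      abort(sprintf("partition is missing %d node(s), e.g. '%s'",
                    length(missing), missing[1]))
    }
    memb <- partition$module[match(ids, partition$node_id)]
  } else {
    if (length(partition) != n) abort("partition length must equal the node count")
    memb <- partition
  }
  if (anyNA(memb)) abort("partition contains missing module labels")
  as.integer(factor(memb))
}

#' Full topology summary with null normalization
#'
#' One Table-style row for a network: observed topology, Louvain
#' modularity, G(n, m) null means, the C/C_R and L/L_R ratios, and the
#' small-world coefficient.
#'
#' @param g igraph graph (at least 2 nodes and 1 edge).
#' @param reps Null-model replicates (default 100).
#' @param seed Seed for both Louvain and the null draws.
#' @param paths Passed to [global_topology()].
#' @return One-row tibble combining observed metrics, null means,
#'   `c_ratio`, `l_ratio`, and `small_world`.
#' @export
topology_summary <- function(g, reps = 100, seed = 1, paths = "connected_pairs") {
  obs <- global_topology(g, paths = paths)
  part <- louvain_modules(g, seed = seed)
  obs$modularity <- attr(part, "modularity")
  null <- er_null(obs$n_nodes, obs$n_edges, reps = reps, seed = seed)
  out <- dplyr::bind_cols(obs, null)
  out$c_ratio <- out$clustering / out$clustering_r
  out$l_ratio <- out$path_length / out$path_length_r
  out$small_world <- small_world(out$clustering, out$clustering_r,
                                 out$path_length, out$path_length_r)
  out
}
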