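# Per-node topology: within-module degree (Zi), among-module connectivity
# (Pi), the four-role taxonomy, centralities, and category comparisons.

#' Within-module degree z-score (Zi)
#'
#' For node i in module s, `Zi = (k_is - mean_s) / sd_s` where `k_is` is
#' the number of i's links into its own module and mean/sd are taken over
#' the members of s (population standard deviation, Guimera-Amaral
#' convention). Modules with zero spread (including singletons) give Zi = 0.
#'
#' @param g igraph graph.
#' @param partition Module assignment (vector or `node_id`/`module` tibble).
#' @return Tibble (`node_id`, `module`, `k_within`, `z_within`).
#' @export
within_module_degree <- function(g, partition) {
  memb <- partition_vector(g, partition)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  k_within <- within_degree_counts(g, memb)$k_within
  z <- numeric(length(memb))
  for (s in unique(memb)) {
    in_s <- memb == s
    mu <- mean(k_within[in_s])
    sdev <- pop_sd(k_within[in_s])
    z[in_s] <- if (is.na(sdev) || sdev == 0) 0 else (k_within[in_s] - mu) / sdev
  }
  tibble(node_id = ids, module = memb, k_within = k_within, z_within = z)
}

#' Among-module connectivity (participation coefficient, Pi)
#'
#' `Pi = 1 - sum_s (k_is / k_i)^2`, the evenness of node i's links over
#' modules: 0 when every link stays inside its own module, approaching 1
#' when links are spread evenly over many modules. Degree-0 nodes get 0.
#'
#' @inheritParams within_module_degree
#' @return Tibble (`node_id`, `module`, `degree`, `p_among`).
#' @export
participation_coefficient <- function(g, partition) {
  memb <- partition_vector(g, partition)
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  k <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  # k_is for every (node, neighbor-module) combination
  p <- numeric(n)
  if (nrow(el) > 0) {
    ends <- rbind(cbind(el[, 1], memb[el[, 2]]), cbind(el[, 2], memb[el[, 1]]))
    tab <- tapply(rep(1, nrow(ends)), list(ends[, 1], ends[, 2]), sum)
    tab[is.na(tab)] <- 0
    touched <- as.integer(rownames(tab))
    p[touched] <- 1 - rowSums((tab / k[touched])^2)
  }
  p[k == 0] <- 0
  tibble(node_id = ids, module = memb, degree = unname(k), p_among = p)
}

within_degree_counts <- function(g, memb) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  k_within <- numeric(n)
  if (nrow(el) > 0) {
    same <- memb[el[, 1]] == memb[el[, 2]]
    inc <- c(el[same, 1], el[same, 2])
    if (length(inc) > 0) {
      t_in <- table(inc)
      k_within[as.integer(names(t_in))] <- as.numeric(t_in)
    }
  }
  list(k_within = k_within)
}

#' Classify nodes into the four-role taxonomy
#'
#' Peripherals (`Zi <= 2.5, Pi <= 0.62`), connectors (`Zi <= 2.5, Pi >
#' 0.62`), module hubs (`Zi > 2.5, Pi <= 0.62`), and network hubs (`Zi >
#' 2.5, Pi > 0.62`).
#'
#' @param z_within,p_among Numeric vectors of Zi and Pi.
#' @param z_threshold,p_threshold Role thresholds (defaults 2.5 and 0.62).
#' @return Character vector of roles.
#' @export
classify_role <- function(z_within, p_among, z_threshold = 2.5, p_threshold = 0.62) {
  dplyr::case_when(
    z_within > z_threshold & p_among > p_threshold ~ "network_hub",
    z_within > z_threshold ~ "module_hub",
    p_among > p_threshold ~ "connector",
    .default = "peripheral"
  )
}

#' Per-node centrality metrics
#'
#' Degree, betweenness (unnormalized by default), closeness in the
#' NetworkAnalyzer convention `(number of reachable nodes) / (sum of
#' distances to them)` (or its harmonic variant), mean neighbor degree
#' (neighborhood connectivity), and mean shortest path to reachable nodes.
#'
#' @param g igraph graph.
#' @param normalized Normalize betweenness (default FALSE).
#' @param harmonic Use harmonic closeness `mean(1/d)` instead (default
#'   FALSE).
#' @return Tibble (`node_id`, `degree`, `betweenness`, `closeness`,
#'   `neighborhood_connectivity`, `avg_shortest_path`).
#' @export
node_centralities <- function(g, normalized = FALSE, harmonic = FALSE) {
  ids <- igraph::V(g)$name
  if (is.null(ids)) ids <- as.character(seq_len(igraph::vcount(g)))
  k <- igraph::degree(g)
  btw <- igraph::betweenness(g, normalized = normalized)
  d <- igraph::distances(g)
  diag(d) <- Inf
  reach <- is.finite(d)
  n_reach <- rowSums(reach)
  sum_d <- rowSums(ifelse(reach, d, 0))
  closeness <- ifelse(n_reach > 0,
                      if (harmonic) rowSums(ifelse(reach, 1 / d, 0)) / (length(ids) - 1)
                      else n_reach / sum_d,
                      0)
  asp <- ifelse(n_reach > 0, sum_d / n_reach, NA_real_)
  adj <- igraph::as_adj_list(g)
  nc <- vapply(seq_along(adj), function(i) {
    nb <- adj[[i]]
    if (length(nb) == 0) NA_real_ else mean(k[as.integer(nb)])
  }, numeric(1))
  tibble(node_id = ids, degree = unname(k), betweenness = unname(btw),
         closeness = as.numeric(closeness),
         neighborhood_connectivity = nc,
         avg_shortest_path = as.numeric(asp))
}

#' Node role table: Zi, Pi, role, and centralities
#'
#' @param g igraph graph.
#' @param partition Module assignment (vector or tibble).
#' @param include_env Keep environment nodes in the role statistics
#'   (default FALSE: roles describe microbes; requires a `kind` vertex
#'   attribute to distinguish).
#' @inheritParams classify_role
#' @return Tibble with `node_id`, `module`, `z_within`, `p_among`, `role`,
#'   and the [node_centralities()] columns.
#' @export
node_roles <- function(g, partition, include_env = FALSE,
                       z_threshold = 2.5, p_threshold = 0.62) {
  zi <- within_module_degree(g, partition)
  pi <- participation_coefficient(g, partition)
  cen <- node_centralities(g)
  out <- zi |>
    dplyr::left_join(dplyr::select(pi, "node_id", "p_among"), by = "node_id") |>
    dplyr::left_join(cen, by = "node_id") |>
    dplyr::mutate(role = classify_role(.data$z_within, .data$p_among,
                                       z_threshold, p_threshold))
  kind <- igraph::vertex_attr(g, "kind")
  if (!include_env && !is.null(kind)) {
    out <- out[kind != "env", , drop = FALSE]
  }
  out
}

#' Pairwise rank-sum comparison of node metrics across niche categories
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests for every metric and
#' every pair of categories, with the conventional significance stars
#' (`*` 0.01 <= p < 0.05, `**` 0.001 <= p < 0.01, `***` p < 0.001).
#' Categories with fewer than 3 nodes are skipped with a warning.
#'
#' @param data Tibble of per-node metrics plus a grouping column.
#' @param category Name of the grouping column (default `"category"`).
#' @param metrics Character vector of metric columns (default: all numeric
#'   columns).
#' @return Tibble (`metric`, `group1`, `group2`, `p`, `stars`).
#' @export
compare_by_category <- function(data, category = "category", metrics = NULL) {
  stopifnot(category %in% names(data))
  if (is.null(metrics)) {
    metrics <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  counts <- table(data[[category]])
  small <- names(counts)[counts < 3]
  if (length(small) > 0) {
    warn(sprintf("skipping category(ies) with < 3 nodes: %s",
                 paste(small, collapse = ", ")))
  }
  groups <- names(counts)[counts >= 3]
  if (length(groups) < 2) abort("need at least 2 categories with >= 3 nodes each")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  purrr::map_dfr(metrics, function(mt) {
    purrr::map_dfr(pairs, function(pr) {
      a <- data[[mt]][data[[category]] == pr[1]]
      b <- data[[mt]][data[[category]] == pr[2]]
      pv <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE)$p.value)
      tibble(metric = mt, group1 = pr[1], group2 = pr[2], p = pv,
             stars = significance_stars(pv))
    })
  })
}

#' Significance stars for p-values
#'
#' @param p Numeric vector.
#' @return `"***"` for p < 0.001, `"**"` for 0.001 <= p < 0.01, `"*"` for
#'   0.01 <= p < 0.05, `""` otherwise.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Role counts per niche category
#'
#' @param roles Output of [node_roles()].
#' @param profiles Optional [niche_profiles()] tibble supplying niche
#'   categories (joined on ASV id); if the roles table already has a
#'   `category` column it is used directly.
#' @return Tibble of counts (`category`, `role`, `n`).
#' @export
role_summary <- function(roles, profiles = NULL) {
  if (!("category" %in% names(roles))) {
    if (is.null(profiles)) abort("supply `profiles` or a `category` column")
    roles <- dplyr::left_join(
      roles, dplyr::select(profiles, "asv_id", "category"),
      by = c(node_id = "asv_id"))
  }
  dplyr::count(roles, .data$category, .data$role, name = "n")
}
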