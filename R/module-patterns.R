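# Module-level summaries: major modules, feature-scaled distribution
# patterns, Ward clustering, environmental correlations, inter-module
# connectivity, and the environment subnetwork.

#' Flag major modules
#'
#' A module is major when its size reaches `max(min_size, min_fraction * n)`
#' where n is the total node count. The rule is a tunable default: datasets
#' differ in how sharply module sizes drop off.
#'
#' @param partition Tibble (`node_id`, `module`) or vector of module labels.
#' @param min_fraction Minimum share of all nodes (default 0.02).
#' @param min_size Absolute minimum size (default 5).
#' @return Tibble (`module`, `size`, `fraction`, `major`), with the share
#'   of nodes in major modules in the `coverage` attribute.
#' @export
major_modules <- function(partition, min_fraction = 0.02, min_size = 5) {
  memb <- if (is.data.frame(partition)) partition$module else partition
  if (length(memb) == 0) abort("empty partition")
  sizes <- table(memb)
  n <- length(memb)
  cut <- max(min_size, min_fraction * n)
  out <- tibble(
    module = names(sizes),
    size = as.integer(sizes),
    fraction = as.integer(sizes) / n,
    major = as.integer(sizes) >= cut
  )
  out$module <- utils::type.convert(out$module, as.is = TRUE)
  attr(out, "coverage") <- sum(out$size[out$major]) / n
  out
}

#' Min-max feature scaling to \[0, 1\]
#'
#' `x' = (x - min) / (max - min)`. A constant vector maps to all zeros with
#' a warning.
#'
#' @param x Numeric vector.
#' @return Scaled vector in `[0, 1]`.
#' @export
feature_scale <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warn("constant vector: feature scaling returns all zeros")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Per-sample distribution patterns of modules
#'
#' Each member ASV's relative abundance profile is min-max scaled across
#' samples, then member profiles are averaged per sample, giving one
#' `[0, 1]` trajectory per module. Environment nodes never contribute;
#' modules with no ASV members are dropped with a warning.
#'
#' @param tbl Feature table tibble (counts by default; converted to
#'   per-sample relative abundances internally).
#' @param partition Tibble (`node_id`, `module`); node ids matching
#'   `tbl$asv_id` are treated as ASVs.
#' @param modules Optional subset of module labels (default: all with ASV
#'   members).
#' @param relative Convert counts to per-sample relative abundances first
#'   (default TRUE); set FALSE when `tbl` already holds abundance profiles.
#' @return Long tibble (`module`, `sample_id`, `pattern`).
#' @export
module_patterns <- function(tbl, partition, modules = NULL, relative = TRUE) {
  m <- ft_matrix(tbl)
  rel <- if (relative) {
    tot <- colSums(m)
    tot[tot == 0] <- 1
    sweep(m, 2, tot, "/")
  } else {
    m
  }
  part <- partition[partition$node_id %in% rownames(rel), , drop = FALSE]
  if (is.null(modules)) modules <- sort(unique(partition$module))
  empty <- setdiff(modules, unique(part$module))
  if (length(empty) > 0) {
    warn(sprintf("module(s) without ASV members dropped: %s",
                 paste(empty, collapse = ", ")))
    modules <- setdiff(modules, empty)
  }
  if (length(modules) == 0) abort("no module has ASV members")
  purrr::map_dfr(modules, function(mod) {
    ids <- part$node_id[part$module == mod]
    scaled <- t(apply(rel[ids, , drop = FALSE], 1, feature_scale))
    tibble(module = mod, sample_id = colnames(rel),
           pattern = unname(colMeans(scaled)))
  })
}

#' Ward dendrogram of module patterns
#'
#' Hierarchical clustering of module distribution patterns on Euclidean
#' distances with Ward linkage (`hclust`'s `ward.D2`, the squared-Euclidean
#' Ward criterion; `ward.D` available via `method`).
#'
#' @param patterns Long tibble from [module_patterns()] or a wide
#'   module-by-sample matrix.
#' @param method `"ward.D2"` (default) or `"ward.D"`.
#' @return An `hclust` object.
#' @export
ward_cluster <- function(patterns, method = c("ward.D2", "ward.D")) {
  method <- match.arg(method)
  w <- pattern_matrix(patterns)
  if (nrow(w) < 2) abort("need at least 2 module patterns to cluster")
  stats::hclust(stats::dist(w), method = method)
}

pattern_matrix <- function(patterns) {
  if (is.matrix(patterns)) return(patterns)
  wide <- tidyr::pivot_wider(patterns, names_from = "sample_id",
                             values_from = "pattern")
  w <- as.matrix(wide[, -1, drop = FALSE])
  rownames(w) <- as.character(wide$module)
  w
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object (e.g. from [ward_cluster()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  writeLines(paste0(hclust_to_newick(hc), ";"), path)
  invisible(path)
}

hclust_to_newick <- function(hc) {
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  build <- function(i, parent_h) {
    if (i < 0) {
      sprintf("%s:%g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%g", build(hc$merge[i, 1], h), build(hc$merge[i, 2], h),
              parent_h - h)
    }
  }
  top <- nrow(hc$merge)
  h <- hc$height[top]
  sprintf("(%s,%s)", build(hc$merge[top, 1], h), build(hc$merge[top, 2], h))
}

#' Spearman correlation of module patterns with environmental covariates
#'
#' @param patterns Long tibble from [module_patterns()].
#' @param metadata Sample metadata tibble (`sample_id` + covariates);
#'   non-numeric covariates are skipped with a warning.
#' @return Tibble (`module`, `covariate`, `rho`, `p`).
#' @export
module_env_correlation <- function(patterns, metadata) {
  w <- pattern_matrix(patterns)
  shared <- intersect(colnames(w), metadata$sample_id)
  if (length(shared) < 4) abort("need at least 4 shared samples")
  w <- w[, shared, drop = FALSE]
  md <- metadata[match(shared, metadata$sample_id), , drop = FALSE]
  covs <- setdiff(names(md), "sample_id")
  non_num <- covs[!vapply(md[covs], is.numeric, logical(1))]
  if (length(non_num) > 0) {
    warn(sprintf("skipping non-numeric covariate(s): %s",
                 paste(non_num, collapse = ", ")))
  }
  covs <- setdiff(covs, non_num)
  env <- t(as.matrix(md[covs]))
  colnames(env) <- shared
  x <- rbind(w, env)
  rownames(x) <- c(paste0("module_", rownames(w)), covs)
  sp <- spearman_all_pairs(x)
  mods <- seq_len(nrow(w))
  idx_env <- nrow(w) + seq_along(covs)
  purrr::map_dfr(mods, function(i) {
    tibble(module = rownames(w)[i],
           covariate = covs,
           rho = sp$rho[i, idx_env],
           p = sp$p[i, idx_env])
  })
}

#' Inter- and intra-module edge counts and densities
#'
#' Within-module density is `e_s / (n_s (n_s - 1) / 2)`; between-module
#' density is `e_st / (n_s * n_t)`. Percentages are rounded half away from
#' zero to one decimal.
#'
#' @param g igraph graph.
#' @param partition Module assignment (vector or tibble).
#' @return Tibble (`module_a`, `module_b`, `n_nodes_a`, `n_nodes_b`,
#'   `n_edges`, `density`, `pct`), one row per unordered module pair
#'   (including `a == b`).
#' @export
intermodule_edges <- function(g, partition) {
  memb <- partition_vector(g, partition)
  sizes <- table(memb)
  mods <- as.integer(names(sizes))
  el <- igraph::as_edgelist(g, names = FALSE)
  ma <- pmin(memb[el[, 1]], memb[el[, 2]])
  mb <- pmax(memb[el[, 1]], memb[el[, 2]])
  purrr::map_dfr(seq_along(mods), function(i) {
    purrr::map_dfr(seq(i, length(mods)), function(j) {
      a <- mods[i]; b <- mods[j]
      ne <- sum(ma == a & mb == b)
      na_ <- as.integer(sizes[as.character(a)])
      nb_ <- as.integer(sizes[as.character(b)])
      dens <- if (a == b) {
        if (na_ < 2) NA_real_ else ne / (na_ * (na_ - 1) / 2)
      } else {
        ne / (na_ * nb_)
      }
      tibble(module_a = a, module_b = b, n_nodes_a = na_, n_nodes_b = nb_,
             n_edges = ne, density = dens,
             pct = round_half_up(100 * dens, 1))
    })
  })
}

#' Environment subnetwork: factors and their directly linked taxa
#'
#' Extracts the subgraph induced by the environment nodes and the ASVs
#' directly linked to them; ASV-ASV edges among those neighbors are
#' excluded by default. Also tabulates, per environment factor, the niche
#' composition of its linked ASVs, and per category the fraction of its
#' network ASVs linked to each factor.
#'
#' @param net A `conetwork` (must contain environment nodes).
#' @param include_asv_asv Keep ASV-ASV edges among selected neighbors
#'   (default FALSE).
#' @return List with `graph` (igraph subgraph) and `composition` tibble
#'   (`env_factor`, `category`, `n_linked`, `frac_of_factor_links`,
#'   `frac_of_category`).
#' @export
env_subnetwork <- function(net, include_asv_asv = FALSE) {
  stopifnot(inherits(net, "conetwork"))
  g <- net$graph
  env_ids <- net$nodes$id[net$nodes$kind == "env"]
  if (length(env_ids) == 0) abort("network contains no environment nodes")
  deg <- igraph::degree(g)
  dangling <- env_ids[deg[env_ids] == 0]
  if (length(dangling) > 0) {
    warn(sprintf("environment factor(s) without edges omitted: %s",
                 paste(dangling, collapse = ", ")))
    env_ids <- setdiff(env_ids, dangling)
  }
  nb <- unique(unlist(lapply(env_ids, function(e) {
    igraph::neighbors(g, e)$name
  })))
  asv_nb <- setdiff(nb, net$nodes$id[net$nodes$kind == "env"])
  sub <- igraph::induced_subgraph(g, c(env_ids, asv_nb))
  if (!include_asv_asv && igraph::ecount(sub) > 0) {
    kinds <- igraph::V(sub)$kind
    el <- igraph::as_edgelist(sub, names = FALSE)
    both_asv <- kinds[el[, 1]] == "asv" & kinds[el[, 2]] == "asv"
    sub <- igraph::delete_edges(sub, which(both_asv))
  }
  cat_of <- if ("category" %in% names(net$nodes)) {
    stats::setNames(net$nodes$category, net$nodes$id)
  } else {
    stats::setNames(rep("asv", nrow(net$nodes)), net$nodes$id)
  }
  cat_totals <- table(cat_of[net$nodes$id[net$nodes$kind == "asv"]])
  comp <- purrr::map_dfr(env_ids, function(e) {
    linked <- setdiff(igraph::neighbors(g, e)$name, env_ids)
    linked <- linked[cat_of[linked] != "env" | is.na(cat_of[linked])]
    if (length(linked) == 0) return(tibble())
    tab <- table(cat_of[linked])
    tibble(env_factor = e,
           category = names(tab),
           n_linked = as.integer(tab),
           frac_of_factor_links = as.integer(tab) / length(linked),
           frac_of_category = as.integer(tab) /
             as.integer(cat_totals[names(tab)]))
  })
  list(graph = sub, composition = comp)
}
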