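# Spearman co-occurrence network construction with FDR edge filtering.

#' Network inclusion filter for ASVs
#'
#' Keeps ASVs observed in at least `min_prevalence` samples and reaching a
#' relative abundance strictly above `min_max_rel_abund` (0.05% by default)
#' in at least one sample.
#'
#' @param tbl Feature table tibble.
#' @param min_prevalence Minimum number of samples with a positive count
#'   (inclusive, default 25).
#' @param min_max_rel_abund Relative-abundance threshold that must be
#'   exceeded in at least one sample (strict, default 5e-4).
#' @return Character vector of retained ASV ids.
#' @export
network_input_filter <- function(tbl, min_prevalence = 25, min_max_rel_abund = 5e-4) {
  m <- ft_matrix(tbl)
  if (nrow(m) == 0) return(character(0))
  tot <- colSums(m)
  tot[tot == 0] <- 1
  rel <- sweep(m, 2, tot, "/")
  keep <- rowSums(m > 0) >= min_prevalence &
    apply(rel, 1, max) > min_max_rel_abund
  rownames(m)[keep]
}

#' All-pairs Spearman correlation with t-approximated p-values
#'
#' Rank correlation from average ranks (midranks under ties), computed over
#' pairwise-complete observations. Two-sided p-values use the t
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of
#' freedom; `|rho| = 1` gives p = 0. Zero-variance variables yield NA
#' correlations and are listed in the `undefined` attribute; pairs with
#' fewer than `min_n` complete observations are not tested.
#'
#' @param x Numeric matrix, variables in rows, samples in columns.
#' @param min_n Minimum complete observations per pair (default 10).
#' @return List with symmetric matrices `rho`, `p`, and `n` (pairwise
#'   sample sizes); `rho` has unit diagonal.
#' @export
spearman_all_pairs <- function(x, min_n = 10) {
  stopifnot(is.matrix(x), ncol(x) >= 4)
  vars <- rownames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(nrow(x)))
  xt <- t(x)
  n_mat <- crossprod(!is.na(xt))
  rho <- suppressWarnings(stats::cor(xt, method = "spearman",
                                     use = "pairwise.complete.obs"))
  undefined <- vars[apply(xt, 2, function(v) {
    v <- v[!is.na(v)]
    length(v) < 2 || stats::sd(v) == 0
  })]
  rho[n_mat < min_n] <- NA_real_
  diag(rho) <- ifelse(vars %in% undefined, NA_real_, 1)
  tstat <- rho * sqrt(pmax(n_mat - 2, 0) / (1 - rho^2))
  p <- 2 * stats::pt(-abs(tstat), df = pmax(n_mat - 2, 1))
  p[abs(rho) >= 1] <- 0
  diag(p) <- 0
  dimnames(rho) <- dimnames(p) <- dimnames(n_mat) <- list(vars, vars)
  structure(list(rho = rho, p = p, n = n_mat), undefined = undefined)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment: q of the i-th smallest p-value
#' is `min over j >= i of m * p_(j) / j`, capped at 1, returned in the input
#' order. NAs (untested pairs) are preserved and do not count toward m.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, elementwise `>= p`.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH", n = sum(ok))
  q
}

#' Assemble a co-occurrence network from correlation matrices
#'
#' Retains an edge between two distinct nodes iff `rho > rho_min`, `p <
#' alpha`, and `q < alpha` (all strict, positive correlations only by
#' default; with `positive_only = FALSE` the magnitude `|rho|` is
#' thresholded instead). Environment-environment edges are kept but flagged
#' (`env_env`) so topology statistics can exclude them; isolated nodes are
#' dropped.
#'
#' @param rho,p,q Symmetric matrices over the same node set.
#' @param node_meta Tibble with columns `id`, `kind` (`"asv"` or `"env"`),
#'   and optionally `category`, taxonomy columns.
#' @param rho_min,alpha Edge thresholds (defaults 0.5 and 0.001).
#' @param positive_only Keep only positive correlations (default TRUE).
#' @param include_env Include environment nodes (default TRUE).
#' @return A `conetwork` object: list with `graph` (igraph), `nodes`,
#'   `edges` tibbles, and `params`.
#' @export
build_network <- function(rho, p, q, node_meta,
                          rho_min = 0.5, alpha = 0.001,
                          positive_only = TRUE, include_env = TRUE) {
  if (!isSymmetric(unname(rho), tol = 1e-12) || !isSymmetric(unname(p), tol = 1e-12)) {
    abort("correlation and p-value matrices must be symmetric")
  }
  ids <- rownames(rho)
  stopifnot(all(ids %in% node_meta$id))
  meta <- node_meta[match(ids, node_meta$id), ]
  if (!include_env) {
    keep <- meta$kind != "env"
    rho <- rho[keep, keep, drop = FALSE]
    p <- p[keep, keep, drop = FALSE]
    q <- q[keep, keep, drop = FALSE]
    meta <- meta[keep, ]
    ids <- ids[keep]
  }
  ut <- upper.tri(rho)
  ii <- row(rho)[ut]
  jj <- col(rho)[ut]
  r <- rho[ut]
  pv <- p[ut]
  qv <- q[ut]
  pass <- !is.na(r) & !is.na(pv) & !is.na(qv) &
    (if (positive_only) r > rho_min else abs(r) > rho_min) &
    pv < alpha & qv < alpha
  edges <- tibble(
    source = ids[ii[pass]],
    target = ids[jj[pass]],
    rho = r[pass], p = pv[pass], q = qv[pass],
    env_env = meta$kind[ii[pass]] == "env" & meta$kind[jj[pass]] == "env"
  )
  used <- ids %in% c(edges$source, edges$target)
  nodes <- as_tibble(meta[used, ])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  out <- list(
    graph = g,
    nodes = nodes,
    edges = edges,
    params = list(rho_min = rho_min, alpha = alpha,
                  positive_only = positive_only, include_env = include_env,
                  n_candidate_nodes = length(ids))
  )
  class(out) <- "conetwork"
  out
}

#' Build a co-occurrence network from a feature table
#'
#' End-to-end convenience wrapper: applies the network inclusion filter,
#' stacks per-sample relative abundances of the retained ASVs with the
#' numeric metadata covariates (environment nodes), computes all-pairs
#' Spearman correlations, applies one Benjamini-Hochberg correction over
#' every tested pair (ASV-ASV, ASV-env and env-env together), and
#' thresholds edges.
#'
#' @param tbl Feature table tibble.
#' @param metadata Optional sample metadata tibble (`sample_id` +
#'   covariates); numeric covariates become environment nodes.
#' @param profiles Optional [niche_profiles()] output supplying node niche
#'   categories; when given, `categories` restricts ASVs to those
#'   categories.
#' @param taxonomy Optional taxonomy tibble joined onto ASV nodes.
#' @param categories Character vector of niche categories to include
#'   (default: all non-excluded when `profiles` is given).
#' @param min_prevalence,min_max_rel_abund Inclusion filter parameters
#'   (see [network_input_filter()]).
#' @inheritParams build_network
#' @return A `conetwork` object.
#' @export
build_conetwork <- function(tbl, metadata = NULL, profiles = NULL,
                            taxonomy = NULL, categories = NULL,
                            min_prevalence = 25, min_max_rel_abund = 5e-4,
                            rho_min = 0.5, alpha = 0.001,
                            positive_only = TRUE, include_env = TRUE) {
  keep <- network_input_filter(tbl, min_prevalence, min_max_rel_abund)
  if (!is.null(profiles)) {
    if (is.null(categories)) categories <- c("generalist", "common", "specialist")
    cat_ids <- profiles$asv_id[profiles$category %in% categories]
    keep <- intersect(keep, cat_ids)
  }
  m <- ft_matrix(tbl)
  tot <- colSums(m)
  tot[tot == 0] <- 1
  rel <- sweep(m, 2, tot, "/")[keep, , drop = FALSE]

  node_meta <- tibble(id = keep, kind = "asv")
  if (!is.null(profiles)) {
    node_meta$category <- profiles$category[match(keep, profiles$asv_id)]
  }
  if (!is.null(taxonomy)) {
    node_meta <- dplyr::left_join(node_meta, taxonomy, by = c(id = "asv_id"))
  }

  x <- rel
  if (!is.null(metadata) && include_env) {
    md <- metadata[match(colnames(rel), metadata$sample_id), ]
    num <- md[vapply(md, is.numeric, logical(1))]
    env <- t(as.matrix(num))
    colnames(env) <- colnames(rel)
    x <- rbind(rel, env)
    node_meta <- dplyr::bind_rows(
      node_meta,
      tibble(id = rownames(env), kind = "env")
    )
  }
  sp <- spearman_all_pairs(x)
  q <- sp$rho
  ut <- upper.tri(sp$p)
  qv <- bh_fdr(sp$p[ut])
  q[ut] <- qv
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  diag(q) <- 0
  build_network(sp$rho, sp$p, q, node_meta,
                rho_min = rho_min, alpha = alpha,
                positive_only = positive_only, include_env = include_env)
}

#' @export
print.conetwork <- function(x, ...) {
  cat(sprintf(
    "<conetwork> %d nodes (%d ASV, %d environment), %d edges (rho > %g, p & q < %g)\n",
    nrow(x$nodes), sum(x$nodes$kind == "asv"), sum(x$nodes$kind == "env"),
    nrow(x$edges), x$params$rho_min, x$params$alpha))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-occurrence network into its edge list
#'
#' @param x A `conetwork`.
#' @param ... Unused.
#' @return Tibble with one row per edge (`source`, `target`, `rho`, `p`,
#'   `q`, `env_env`).
#' @exportS3Method generics::tidy
tidy.conetwork <- function(x, ...) {
  x$edges
}

#' One-row summary of a co-occurrence network
#'
#' @param x A `conetwork`.
#' @param ... Unused.
#' @return Tibble with node/edge counts and density.
#' @exportS3Method generics::glance
glance.conetwork <- function(x, ...) {
  n <- nrow(x$nodes)
  m <- nrow(x$edges)
  tibble(
    n_nodes = n,
    n_asv_nodes = sum(x$nodes$kind == "asv"),
    n_env_nodes = sum(x$nodes$kind == "env"),
    n_edges = m,
    n_env_env_edges = sum(x$edges$env_env),
    density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_
  )
}

#' Extract the analysis graph from a co-occurrence network
#'
#' Returns the igraph object used for topology statistics:
#' environment-environment edges are dropped by default (they are flagged,
#' not analyzed), environment nodes optionally removed, and nodes left
#' isolated by the edge filtering discarded.
#'
#' @param net A `conetwork`.
#' @param drop_env_env Remove environment-environment edges (default TRUE).
#' @param drop_env_nodes Remove environment nodes entirely (default FALSE).
#' @return An igraph graph.
#' @export
conetwork_graph <- function(net, drop_env_env = TRUE, drop_env_nodes = FALSE) {
  g <- net$graph
  if (drop_env_env && igraph::ecount(g) > 0) {
    g <- igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$env_env])
  }
  if (drop_env_nodes) {
    g <- igraph::delete_vertices(g, igraph::V(g)[igraph::V(g)$kind == "env"])
  }
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  g
}

#' Export a network as GraphML plus Cytoscape-style TSV pair
#'
#' Writes `<stem>.graphml`, `<stem>_edges.tsv` (source, target, rho, p, q)
#' and `<stem>_nodes.tsv` (id, kind, category, taxonomy, module when
#' available).
#'
#' @param net A `conetwork`.
#' @param stem Output path stem.
#' @param partition Optional module assignment tibble (`node_id`, `module`)
#'   merged into the node table.
#' @return `stem`, invisibly.
#' @export
export_conetwork <- function(net, stem, partition = NULL) {
  nodes <- net$nodes
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, partition, by = c(id = "node_id"))
  }
  igraph::write_graph(net$graph, paste0(stem, ".graphml"), format = "graphml")
  readr::write_tsv(net$edges, paste0(stem, "_edges.tsv"), progress = FALSE)
  readr::write_tsv(nodes, paste0(stem, "_nodes.tsv"), progress = FALSE)
  invisible(stem)
}
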