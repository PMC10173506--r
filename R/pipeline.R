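# End-to-end orchestration: simulate/read -> filter -> classify -> networks
# -> topology -> roles -> modules, with a run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter with the conventional defaults: low-count
#' threshold 4; niche filters (mean relative abundance >= 2e-5, prevalence
#' >= 25) and cutoffs B > 78 / B < 22; network thresholds rho > 0.5, p and
#' q < 0.001, positive edges only; 100 Erdos-Renyi null replicates; role
#' thresholds Zi 2.5 / Pi 0.62; major-module rule max(5, 2% of nodes).
#'
#' @param scenario A [scenario_config()] to simulate from, or NULL when
#'   reading files.
#' @param feature_table,taxonomy,metadata Input TSV paths (used when
#'   `scenario` is NULL).
#' @param seed Master seed; stage seeds are derived from it.
#' @param min_total Low-count removal threshold.
#' @param min_mean_rel_abund,min_prevalence Niche inclusion filters.
#' @param upper,lower Niche category cutoffs.
#' @param niche_thresholds `"fixed"` or `"data"` (see [niche_profiles()]).
#' @param rho_min,alpha,positive_only Edge thresholds.
#' @param net_min_prevalence,net_min_max_rel_abund Network inclusion
#'   filters.
#' @param null_reps Erdos-Renyi null replicates per network.
#' @param z_threshold,p_threshold Node-role thresholds.
#' @param major_min_fraction,major_min_size Major-module rule.
#' @param networks Which networks to build (subset of
#'   `c("generalist", "common", "specialist", "total")`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            feature_table = NULL, taxonomy = NULL, metadata = NULL,
                            seed = 1,
                            min_total = 4,
                            min_mean_rel_abund = 2e-5, min_prevalence = 25,
                            upper = 78, lower = 22,
                            niche_thresholds = "fixed",
                            rho_min = 0.5, alpha = 0.001, positive_only = TRUE,
                            net_min_prevalence = 25, net_min_max_rel_abund = 5e-4,
                            null_reps = 100,
                            z_threshold = 2.5, p_threshold = 0.62,
                            major_min_fraction = 0.02, major_min_size = 5,
                            networks = c("generalist", "common", "specialist", "total")) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$lower >= cfg$upper) {
    abort("invalid config: niche `upper` cutoff must exceed `lower`")
  }
  if (cfg$alpha <= 0 || cfg$alpha > 1) abort("invalid config: alpha outside (0, 1]")
  if (cfg$rho_min < 0 || cfg$rho_min >= 1) abort("invalid config: rho_min outside [0, 1)")
  if (is.null(cfg$scenario) && is.null(cfg$feature_table)) {
    abort("invalid config: provide a scenario or a feature_table path")
  }
  bad <- setdiff(cfg$networks, c("generalist", "common", "specialist", "total"))
  if (length(bad) > 0) abort(sprintf("unknown network(s): %s", paste(bad, collapse = ", ")))
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a `scenario` block
#' maps to [scenario_config()] arguments.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read YAML configs")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$scenario)) {
    raw$scenario <- do.call(scenario_config, raw$scenario)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/read -> low-count filter -> niche classification ->
#' co-occurrence networks (per niche category plus the total network) ->
#' null-normalized topology -> Louvain modules -> node roles -> module
#' patterns, environment correlations and the environment subnetwork.
#' Identical config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Optional directory for TSV/GraphML/JSON outputs.
#' @return A list of class `niche_pipeline` holding every stage result and
#'   a `manifest` of per-stage counts.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$scenario)) {
    sim <- stage("simulate", simulate_community(config$scenario, seed = config$seed))
    tbl <- sim$table; taxonomy <- sim$taxonomy; metadata <- sim$metadata
    truth <- sim$truth
  } else {
    tbl <- stage("read", read_feature_table(config$feature_table))
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy) else NULL
    metadata <- if (!is.null(config$metadata)) read_sample_metadata(config$metadata) else NULL
    truth <- NULL
  }
  n_asv_raw <- nrow(tbl)

  # --- filtering and classification ----------------------------------------
  tbl_f <- stage("filter_low_count", filter_low_count(tbl, config$min_total))
  profiles <- stage("niche_profiles", niche_profiles(
    tbl_f,
    min_mean_rel_abund = config$min_mean_rel_abund,
    min_prevalence = config$min_prevalence,
    upper = config$upper, lower = config$lower,
    thresholds = config$niche_thresholds))
  cat_summary <- stage("category_summary", category_summary(profiles, tbl_f))

  # --- networks -------------------------------------------------------------
  build_one <- function(cats) {
    build_conetwork(tbl_f, metadata = metadata, profiles = profiles,
                    taxonomy = taxonomy, categories = cats,
                    min_prevalence = config$net_min_prevalence,
                    min_max_rel_abund = config$net_min_max_rel_abund,
                    rho_min = config$rho_min, alpha = config$alpha,
                    positive_only = config$positive_only)
  }
  wanted <- config$networks
  nets <- list()
  for (nm in wanted) {
    cats <- if (nm == "total") c("generalist", "common", "specialist") else nm
    nets[[nm]] <- stage(paste0("network_", nm), build_one(cats))
  }

  # --- topology + null ------------------------------------------------------
  topology <- purrr::imap_dfr(nets, function(net, nm) {
    g <- conetwork_graph(net, drop_env_env = TRUE)
    if (igraph::vcount(g) < 2 || igraph::ecount(g) < 1) {
      warn(sprintf("network '%s' too small for topology statistics", nm))
      return(tibble(network = nm, n_nodes = igraph::vcount(g),
                    n_edges = igraph::ecount(g)))
    }
    dplyr::bind_cols(
      tibble(network = nm),
      topology_summary(g, reps = config$null_reps, seed = config$seed + 1L))
  })

  # --- modules and roles on the total network -------------------------------
  total_net <- nets[["total"]] %||% nets[[length(nets)]]
  g_total <- conetwork_graph(total_net, drop_env_env = TRUE)
  partition <- stage("louvain", louvain_modules(g_total, seed = config$seed + 2L))
  majors <- major_modules(partition,
                          min_fraction = config$major_min_fraction,
                          min_size = config$major_min_size)
  roles <- stage("node_roles", node_roles(
    g_total, partition,
    z_threshold = config$z_threshold, p_threshold = config$p_threshold))
  roles <- dplyr::left_join(
    roles, dplyr::select(profiles, "asv_id", "category"),
    by = c(node_id = "asv_id"))
  roles_summary <- dplyr::count(roles, .data$category, .data$role, name = "n")
  role_tests <- tryCatch(
    compare_by_category(
      dplyr::select(roles, "category", "z_within", "p_among", "degree",
                    "betweenness", "closeness", "neighborhood_connectivity",
                    "avg_shortest_path"),
      category = "category"),
    error = function(e) NULL)

  patterns <- stage("module_patterns", module_patterns(
    tbl_f, partition, modules = majors$module[majors$major]))
  dend <- if (length(unique(patterns$module)) >= 2) ward_cluster(patterns) else NULL
  env_rho <- if (!is.null(metadata)) {
    stage("module_env_correlation", module_env_correlation(patterns, metadata))
  } else {
    NULL
  }
  inter <- stage("intermodule_edges", intermodule_edges(g_total, partition))
  envnet <- if (any(total_net$nodes$kind == "env")) {
    stage("env_subnetwork", env_subnetwork(total_net))
  } else {
    NULL
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nichewebs")),
    seed = config$seed,
    config_hash = rlang::hash(config),
    n_asvs_raw = n_asv_raw,
    n_asvs_after_low_count = nrow(tbl_f),
    n_samples = ncol(tbl_f) - 1L,
    n_included = sum(profiles$category != "excluded"),
    category_counts = stats::setNames(cat_summary$n_asvs, cat_summary$category),
    niche_thresholds = attr(profiles, "thresholds"),
    networks = purrr::imap(nets, function(net, nm) {
      list(nodes = nrow(net$nodes), edges = nrow(net$edges))
    }),
    n_modules = attr(partition, "n_modules"),
    modularity = attr(partition, "modularity"),
    n_major_modules = sum(majors$major),
    major_coverage = attr(majors, "coverage"),
    role_counts = table(roles$role)
  )

  out <- list(
    config = config,
    table = tbl_f,
    metadata = metadata,
    taxonomy = taxonomy,
    truth = truth,
    profiles = profiles,
    category_summary = cat_summary,
    networks = nets,
    topology = topology,
    partition = partition,
    major_modules = majors,
    roles = roles,
    role_summary = roles_summary,
    role_tests = role_tests,
    module_patterns = patterns,
    dendrogram = dend,
    module_env_correlation = env_rho,
    intermodule_edges = inter,
    env_subnetwork = envnet,
    manifest = manifest
  )
  class(out) <- "niche_pipeline"
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_outputs <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(x$table, file.path(outdir, "feature_table_filtered.tsv"))
  readr::write_tsv(x$profiles, file.path(outdir, "niche_profiles.tsv"), progress = FALSE)
  readr::write_tsv(x$topology, file.path(outdir, "topology.tsv"), progress = FALSE)
  readr::write_tsv(x$roles, file.path(outdir, "node_roles.tsv"), progress = FALSE)
  readr::write_tsv(x$role_summary, file.path(outdir, "role_summary.tsv"), progress = FALSE)
  readr::write_tsv(x$module_patterns, file.path(outdir, "module_patterns.tsv"), progress = FALSE)
  readr::write_tsv(x$intermodule_edges, file.path(outdir, "intermodule_edges.tsv"),
                   progress = FALSE)
  if (!is.null(x$module_env_correlation)) {
    readr::write_tsv(x$module_env_correlation, file.path(outdir, "module_env_rho.tsv"),
                     progress = FALSE)
  }
  if (!is.null(x$dendrogram)) {
    write_dendrogram_newick(x$dendrogram, file.path(outdir, "module_dendrogram.nwk"))
  }
  for (nm in names(x$networks)) {
    export_conetwork(x$networks[[nm]], file.path(outdir, paste0("network_", nm)),
                     partition = if (nm == "total") x$partition else NULL)
  }
  if (!is.null(x$env_subnetwork)) {
    igraph::write_graph(x$env_subnetwork$graph,
                        file.path(outdir, "env_subnetwork.graphml"),
                        format = "graphml")
  }
  manifest <- x$manifest
  manifest$role_counts <- as.list(manifest$role_counts)
  manifest$category_counts <- as.list(manifest$category_counts)
  manifest$niche_thresholds <- as.list(manifest$niche_thresholds)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.niche_pipeline <- function(x, ...) {
  report(x)
  invisible(x)
}

#' Human-readable pipeline report
#'
#' Prints the stage counts, the niche category summary, one topology row
#' per constructed network (with its small-world coefficient), role counts,
#' and major-module coverage.
#'
#' @param x A `niche_pipeline` from [run_pipeline()].
#' @return `x`, invisibly.
#' @export
report <- function(x) {
  stopifnot(inherits(x, "niche_pipeline"))
  mf <- x$manifest
  cat("== nichewebs pipeline run ==\n")
  cat(sprintf("ASVs: %d raw -> %d after low-count filter -> %d included\n",
              mf$n_asvs_raw, mf$n_asvs_after_low_count, mf$n_included))
  cat(sprintf("Samples: %d; seed %d\n", mf$n_samples, mf$seed))
  cat("\n-- niche categories --\n")
  print(as.data.frame(x$category_summary), row.names = FALSE)
  empty <- setdiff(c("generalist", "common", "specialist"),
                   x$category_summary$category[x$category_summary$n_asvs > 0])
  if (length(empty) > 0) {
    cat(sprintf("  (empty categories: %s)\n", paste(empty, collapse = ", ")))
  }
  cat("\n-- network topology (observed / ER-null normalized) --\n")
  cols <- intersect(c("network", "n_nodes", "n_edges", "density", "modularity",
                      "clustering", "path_length", "c_ratio", "l_ratio",
                      "small_world"), names(x$topology))
  print(as.data.frame(x$topology[, cols]), row.names = FALSE, digits = 3)
  cat("\n-- node roles (total network) --\n")
  print(as.data.frame(x$role_summary), row.names = FALSE)
  cat(sprintf("\nModules: %d (Q = %.3f); %d major covering %.0f%% of nodes\n",
              mf$n_modules, mf$modularity, mf$n_major_modules,
              100 * mf$major_coverage))
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `niche_pipeline`.
#' @param ... Unused.
#' @return Tibble with headline counts and the total network's topology.
#' @exportS3Method generics::glance
glance.niche_pipeline <- function(x, ...) {
  mf <- x$manifest
  tot <- x$topology[x$topology$network == "total", , drop = FALSE]
  tibble(
    n_asvs_raw = mf$n_asvs_raw,
    n_included = mf$n_included,
    n_generalist = unname(mf$category_counts["generalist"] %||% 0L),
    n_common = unname(mf$category_counts["common"] %||% 0L),
    n_specialist = unname(mf$category_counts["specialist"] %||% 0L),
    n_nodes_total = if (nrow(tot) > 0) tot$n_nodes else NA_integer_,
    n_edges_total = if (nrow(tot) > 0) tot$n_edges else NA_integer_,
    modularity = mf$modularity,
    small_world = if (nrow(tot) > 0 && "small_world" %in% names(tot)) {
      tot$small_world
    } else {
      NA_real_
    }
  )
}
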