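# Synthetic elevation-gradient communities with full ground truth.
#
# The generator manufactures exactly the statistical structure the analysis
# assumes: an elevation gradient sampled in three strata, ~15 environmental
# covariates that track elevation, a latent vegetation variable, and a causal
# cascade environment -> vegetation -> generalists -> common taxa ->
# specialists. Occupancy breadth is controlled by Gaussian niche responses
# along elevation (broad for generalists, narrow for specialists), and
# co-occurrence modules are planted through shared log-scale latent factors.

#' Scenario configuration for the synthetic community generator
#'
#' Defaults encode the study design the pipeline targets: 225 samples split
#' evenly over low/mid/high elevation strata (means 162, 251, 302 m; sd 43,
#' 21, 39), covariates whose elevation trends match the field pattern
#' (moisture and vascular plant cover high at low elevation, temperature,
#' cryptogam cover, rock cover and dry/wet weight ratio high at high
#' elevation, pH flat around 5.1), and desk-scale ASV counts chosen for
#' recoverability of the planted structure.
#'
#' @param n_samples Total samples (split as evenly as possible over 3 strata).
#' @param stratum_elevation_mean,stratum_elevation_sd Per-stratum elevation
#'   means and standard deviations in metres (low, mid, high).
#' @param covariates Data frame with columns `name`, `intercept`, `slope`
#'   (per unit of standardized elevation), `sd`, and `clamp01` (logical:
#'   clamp to \[0, 100\] for percentage covers).
#' @param n_generalist,n_common,n_specialist ASVs per true niche category
#'   carrying planted module structure.
#' @param n_background Module-free common taxa (moderate niche response,
#'   independent optima, no shared factor). They emulate the bulk of a real
#'   community that never enters a co-occurrence module and keep the
#'   community total stable.
#' @param n_rare Additional near-zero ASVs (1-3 total reads) exercising the
#'   low-count filter.
#' @param width_generalist,width_common,width_specialist Gaussian niche
#'   widths (m) along elevation; the generalist width exceeds the gradient
#'   range so generalist occupancy is near-uniform.
#' @param beta_veg_generalist Log-scale coefficient of generalist abundance
#'   on latent vegetation.
#' @param beta_generalist_common Coefficient of common taxa on the
#'   generalist latent.
#' @param beta_common_specialist Coefficient of specialists on the common
#'   latent.
#' @param n_modules Number of planted co-occurrence modules (blocks live in
#'   the common and specialist taxa; generalist co-occurrence arises from the
#'   shared vegetation response instead).
#' @param module_loading Named vector of log-scale loadings on the module
#'   latent factor (`common`, `specialist`).
#' @param sigma_eps Named vector of residual log-scale noise sd per category.
#' @param baseline_mean Named vector of mean log-baseline abundance per
#'   category.
#' @param baseline_sd Sd of per-ASV log-baselines.
#' @param depth_meanlog,depth_sdlog Log-normal sequencing-depth parameters.
#' @param nb_size Negative-binomial size (overdispersion) for counts.
#'
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_samples = 225,
                            stratum_elevation_mean = c(low = 162, mid = 251, high = 302),
                            stratum_elevation_sd = c(low = 43, mid = 21, high = 39),
                            covariates = default_covariate_model(),
                            n_generalist = 40,
                            n_common = 125,
                            n_specialist = 45,
                            n_background = 80,
                            n_rare = 20,
                            width_generalist = 600,
                            width_common = 35,
                            width_specialist = 8,
                            width_background = 35,
                            beta_veg_generalist = 0.5,
                            beta_generalist_common = 0.4,
                            beta_common_specialist = 0.4,
                            n_modules = 4,
                            module_loading = c(common = 2.2, specialist = 2.4),
                            sigma_eps = c(generalist = 0.35, common = 0.3, specialist = 0.3,
                                          background = 0.6),
                            baseline_mean = c(generalist = 1.5, common = 0.7, specialist = 0.7,
                                              background = 1.4),
                            baseline_sd = 0.6,
                            depth_meanlog = log(34000),
                            depth_sdlog = 0.15,
                            nb_size = 10) {
  cfg <- list(
    n_samples = n_samples,
    stratum_elevation_mean = stratum_elevation_mean,
    stratum_elevation_sd = stratum_elevation_sd,
    covariates = covariates,
    n_generalist = n_generalist,
    n_common = n_common,
    n_specialist = n_specialist,
    n_background = n_background,
    n_rare = n_rare,
    width_generalist = width_generalist,
    width_common = width_common,
    width_specialist = width_specialist,
    width_background = width_background,
    beta_veg_generalist = beta_veg_generalist,
    beta_generalist_common = beta_generalist_common,
    beta_common_specialist = beta_common_specialist,
    n_modules = n_modules,
    module_loading = module_loading,
    sigma_eps = sigma_eps,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    depth_meanlog = depth_meanlog,
    depth_sdlog = depth_sdlog,
    nb_size = nb_size
  )
  if (n_samples < 3) abort("scenario needs at least 3 samples (one per stratum)")
  if (any(c(n_generalist, n_common, n_specialist, n_background, n_rare) < 0)) {
    abort("category counts must be non-negative")
  }
  if (any(c(width_generalist, width_common, width_specialist) <= 0)) {
    abort("niche widths must be positive")
  }
  if (n_modules < 1) abort("need at least one planted module")
  structure(cfg, class = "scenario_config")
}

#' Default covariate-on-elevation model
#'
#' One row per environmental covariate: value = intercept + slope * z +
#' Gaussian noise, where z is standardized elevation. Signs follow the
#' field pattern along an Arctic tundra slope (moisture and vascular plant
#' cover decline with elevation; temperature, cryptogam cover, rock cover
#' and dry/wet weight ratio increase; pH is flat).
#'
#' @return A tibble with columns `name`, `intercept`, `slope`, `sd`,
#'   `clamp01`.
#' @export
default_covariate_model <- function() {
  tibble::tribble(
    ~name,                  ~intercept, ~slope, ~sd,  ~clamp01,
    "soil_temperature",     13.6,       2.3,    0.8,  FALSE,
    "moisture",             38,        -10,     5,    TRUE,
    "ph",                   5.1,        0,      0.3,  FALSE,
    "ec",                   0.20,      -0.03,   0.04, FALSE,
    "carbon",               8,         -1.5,    1,    FALSE,
    "nitrogen",             0.6,       -0.1,    0.08, FALSE,
    "cn_ratio",             13.1,      -1.8,    1.5,  FALSE,
    "litter_depth",         2.5,       -1.0,    0.5,  FALSE,
    "vascular_plant_cover", 45,        -22,     8,    TRUE,
    "cryptogam_cover",      35,         15,     8,    TRUE,
    "rock_cover",           20,         12,     6,    TRUE,
    "dry_wet_ratio",        0.55,       0.12,   0.05, FALSE,
    "respiration",          1.0,        0.3,    0.15, FALSE,
    "altitude",             NA,         NA,     2,    FALSE  # elevation + noise
  )
}

#' Generate a synthetic community with ground truth
#'
#' Draws sample metadata, a latent vegetation variable, per-ASV expected
#' abundances `exp(baseline + niche response + cascade effect + module
#' factor + noise)`, and negative-binomial counts at a log-normal
#' sequencing depth. The same seed always yields identical output.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `community_sim` with elements `table` (feature
#'   table tibble), `taxonomy`, `metadata`, and `truth` (per-ASV true
#'   category, planted module, niche optimum/width, baseline; the per-sample
#'   latent vegetation is in `metadata$latent_vegetation`).
#' @export
simulate_community <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  with_seed_(seed, simulate_community_(config))
}

simulate_community_ <- function(cfg) {
  n <- cfg$n_samples
  strata <- rep(c("low", "mid", "high"), length.out = 3)
  per <- diff(floor(seq(0, n, length.out = 4)))
  stratum <- rep(strata, times = per)
  elevation <- stats::rnorm(n,
                            mean = cfg$stratum_elevation_mean[stratum],
                            sd = cfg$stratum_elevation_sd[stratum])
  sample_id <- sprintf("S%03d", seq_len(n))
  z <- as.numeric(scale(elevation))

  cov_tbl <- cfg$covariates
  covs <- list()
  for (i in seq_len(nrow(cov_tbl))) {
    nm <- cov_tbl$name[i]
    if (nm == "altitude") {
      v <- elevation + stats::rnorm(n, 0, cov_tbl$sd[i])
    } else {
      v <- cov_tbl$intercept[i] + cov_tbl$slope[i] * z + stats::rnorm(n, 0, cov_tbl$sd[i])
    }
    if (isTRUE(cov_tbl$clamp01[i])) v <- pmin(100, pmax(0, v))
    covs[[nm]] <- v
  }

  # Latent vegetation: indicated by vascular plant and cryptogam cover
  # (vascular-dominated), plus noise; standardized.
  veg_raw <- 0.9 * as.numeric(scale(covs$vascular_plant_cover)) +
    0.15 * as.numeric(scale(covs$cryptogam_cover)) +
    stats::rnorm(n, 0, 0.25)
  veg <- as.numeric(scale(veg_raw))

  metadata <- dplyr::bind_cols(
    tibble(sample_id = sample_id, stratum = stratum, elevation = elevation),
    tibble::as_tibble(covs),
    tibble(latent_vegetation = veg)
  )

  # Planted modules: shared latent factor per module plus a module-specific
  # elevation optimum (modules are correlation blocks, as in real data where
  # module membership tracks habitat preference).
  K <- cfg$n_modules
  mod_opt <- stats::quantile(elevation, probs = seq(0.1, 0.9, length.out = K),
                             names = FALSE, type = 7)
  F_mod <- matrix(stats::rnorm(K * n), nrow = K)
  if (K > 1) {
    # Zero-sum across modules within each sample: modules trade off, so the
    # community total stays stable and blocks are mutually decorrelated.
    F_mod <- sweep(F_mod, 2, colMeans(F_mod))
  }

  categories <- c(rep("generalist", cfg$n_generalist),
                  rep("common", cfg$n_common),
                  rep("specialist", cfg$n_specialist))
  n_asv <- length(categories)
  # Blocks are planted in common taxa and specialists only: generalist
  # co-occurrence is vegetation-driven (the cascade), not block-driven,
  # so generalists carry no planted module id.
  module <- rep_len(seq_len(K), n_asv)
  module <- unsplit(lapply(split(module, categories), sample), categories)
  module[categories == "generalist"] <- NA_integer_
  widths <- c(generalist = cfg$width_generalist,
              common = cfg$width_common,
              specialist = cfg$width_specialist)[categories]
  # Blocks are habitat patches: members share the block's elevation optimum
  # (with jitter) as well as its latent factor; generalists are flat across
  # the gradient.
  opt <- ifelse(categories == "generalist",
                stats::median(elevation),
                mod_opt[ifelse(is.na(module), 1L, module)] +
                  stats::rnorm(n_asv, 0, ifelse(categories == "common", 20, 10)))
  baseline <- stats::rnorm(n_asv, cfg$baseline_mean[categories], cfg$baseline_sd)

  niche <- -(outer(opt, elevation, "-"))^2 / (2 * widths^2)  # n_asv x n

  eta <- matrix(0, n_asv, n)
  g_idx <- which(categories == "generalist")
  c_idx <- which(categories == "common")
  s_idx <- which(categories == "specialist")

  add_noise <- function(idx) {
    matrix(stats::rnorm(length(idx) * n, 0, cfg$sigma_eps[categories[idx[1]]]),
           nrow = length(idx))
  }
  lam <- cfg$module_loading

  if (length(g_idx) > 0) {
    eta[g_idx, ] <- baseline[g_idx] + niche[g_idx, , drop = FALSE] +
      cfg$beta_veg_generalist * matrix(veg, length(g_idx), n, byrow = TRUE) +
      add_noise(g_idx)
  }
  g_latent <- if (length(g_idx) > 0) {
    as.numeric(scale(colMeans(eta[g_idx, , drop = FALSE])))
  } else {
    rep(0, n)
  }
  if (length(c_idx) > 0) {
    eta[c_idx, ] <- baseline[c_idx] + niche[c_idx, , drop = FALSE] +
      cfg$beta_generalist_common * matrix(g_latent, length(c_idx), n, byrow = TRUE) +
      lam["common"] * F_mod[module[c_idx], , drop = FALSE] +
      add_noise(c_idx)
  }
  c_latent <- if (length(c_idx) > 0) {
    as.numeric(scale(colMeans(eta[c_idx, , drop = FALSE])))
  } else {
    rep(0, n)
  }
  if (length(s_idx) > 0) {
    eta[s_idx, ] <- baseline[s_idx] + niche[s_idx, , drop = FALSE] +
      cfg$beta_common_specialist * matrix(c_latent, length(s_idx), n, byrow = TRUE) +
      lam["specialist"] * F_mod[module[s_idx], , drop = FALSE] +
      add_noise(s_idx)
  }

  # Background common taxa: moderate niche responses with independent
  # optima, no shared module factor. They carry the community mass a real
  # dataset holds outside any co-occurrence module.
  nb <- cfg$n_background
  if (nb > 0) {
    bg_opt <- stats::runif(nb, min(elevation), max(elevation))
    bg_baseline <- stats::rnorm(nb, cfg$baseline_mean["background"], cfg$baseline_sd)
    bg_niche <- -(outer(bg_opt, elevation, "-"))^2 / (2 * cfg$width_background^2)
    bg_eta <- bg_baseline + bg_niche +
      matrix(stats::rnorm(nb * n, 0, cfg$sigma_eps["background"]), nb, n)
    eta <- rbind(eta, bg_eta)
    categories <- c(categories, rep("background", nb))
    module <- c(module, rep(NA_integer_, nb))
    opt <- c(opt, bg_opt)
    widths <- c(widths, rep(cfg$width_background, nb))
    baseline <- c(baseline, bg_baseline)
    n_asv <- n_asv + nb
  }

  # Compositional counts: expected proportions within each sample, scaled to
  # a log-normal depth, with negative-binomial overdispersion.
  lambda <- exp(eta)
  props <- sweep(lambda, 2, colSums(lambda), "/")
  depth <- round(stats::rlnorm(n, cfg$depth_meanlog, cfg$depth_sdlog))
  mu <- sweep(props, 2, depth, "*")
  counts <- matrix(stats::rnbinom(n_asv * n, mu = mu, size = cfg$nb_size),
                   n_asv, n)

  # Rare ASVs: 1-3 reads in total, exercising the low-count removal rule.
  if (cfg$n_rare > 0) {
    rare <- matrix(0L, cfg$n_rare, n)
    for (r in seq_len(cfg$n_rare)) {
      tot <- sample(1:3, 1)
      at <- sample.int(n, tot, replace = TRUE)
      for (a in at) rare[r, a] <- rare[r, a] + 1L
    }
    counts <- rbind(counts, rare)
  }

  asv_id <- sprintf("ASV%04d", seq_len(nrow(counts)))
  rownames(counts) <- asv_id
  colnames(counts) <- sample_id

  truth <- tibble(
    asv_id = asv_id,
    category = c(categories, rep("rare", cfg$n_rare)),
    module = c(module, rep(NA_integer_, cfg$n_rare)),
    niche_optimum = c(opt, rep(NA_real_, cfg$n_rare)),
    niche_width = c(unname(widths), rep(NA_real_, cfg$n_rare)),
    baseline = c(baseline, rep(NA_real_, cfg$n_rare))
  )

  taxonomy <- synthetic_taxonomy(truth)

  out <- list(
    table = ft_tibble(counts),
    taxonomy = taxonomy,
    metadata = metadata,
    truth = truth,
    coefficients = list(
      beta_veg_generalist = cfg$beta_veg_generalist,
      beta_generalist_common = cfg$beta_generalist_common,
      beta_common_specialist = cfg$beta_common_specialist,
      module_loading = cfg$module_loading
    )
  )
  class(out) <- "community_sim"
  out
}

# Plausible (synthetic) taxonomy strings whose order-level pools mirror the
# groups typical of tundra soils for each niche category.
synthetic_taxonomy <- function(truth) {
  pools <- list(
    generalist = c("Rhizobiales", "Sphingomonadales", "Acidobacteriales"),
    common = c("Chthoniobacterales", "Burkholderiales", "Solirubrobacterales",
               "Cytophagales"),
    specialist = c("Ktedonobacterales", "Tepidisphaerales", "Chitinophagales"),
    background = c("Gemmatales", "Pyrinomonadales", "Solirubrobacterales"),
    rare = c("unclassified")
  )
  phyla <- c(Rhizobiales = "Proteobacteria", Sphingomonadales = "Proteobacteria",
             Acidobacteriales = "Acidobacteriota", Chthoniobacterales = "Verrucomicrobiota",
             Burkholderiales = "Proteobacteria", Solirubrobacterales = "Actinobacteriota",
             Cytophagales = "Bacteroidota", Ktedonobacterales = "Chloroflexi",
             Tepidisphaerales = "Planctomycetota", Chitinophagales = "Bacteroidota",
             Gemmatales = "Planctomycetota", Pyrinomonadales = "Acidobacteriota",
             unclassified = "unclassified")
  ord <- vapply(truth$category, function(cat) {
    pool <- pools[[cat]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  tibble(
    asv_id = truth$asv_id,
    domain = "Bacteria",
    phylum = unname(phyla[ord]),
    class = paste0(unname(phyla[ord]), "_c"),
    order = unname(ord),
    family = paste0(unname(ord), "_f"),
    genus = paste0(unname(ord), "_g", seq_len(nrow(truth)))
  )
}

#' Write the simulated tables to a directory
#'
#' Exports `feature_table.tsv`, `taxonomy.tsv`, `metadata.tsv`, and
#' `ground_truth.tsv` in the same dialect the readers expect.
#'
#' @param sim A `community_sim` from [simulate_community()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_community <- function(sim, dir) {
  stopifnot(inherits(sim, "community_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(sim$table, file.path(dir, "feature_table.tsv"))
  readr::write_tsv(sim$taxonomy, file.path(dir, "taxonomy.tsv"), progress = FALSE)
  readr::write_tsv(sim$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "ground_truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Planted-partition random graph
#'
#' Undirected graph on `n_nodes` split evenly into `n_modules` blocks;
#' within-block edges appear with probability `p_in`, between-block edges
#' with `p_out`. Used as a fixture for module-recovery tests.
#'
#' @param n_nodes,n_modules Node and block counts.
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed Integer seed.
#' @return An igraph graph with vertex attribute `block`.
#' @export
planted_partition_graph <- function(n_nodes, n_modules, p_in, p_out, seed = 1) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, n_modules >= 1,
            n_nodes >= n_modules)
  block <- rep_len(seq_len(n_modules), n_nodes)
  with_seed_(seed, {
    pairs <- utils::combn(n_nodes, 2)
    same <- block[pairs[1, ]] == block[pairs[2, ]]
    prob <- ifelse(same, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < prob
    g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
    if (any(keep)) g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
    igraph::V(g)$name <- paste0("n", seq_len(n_nodes))
    igraph::V(g)$block <- block
    g
  })
}
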