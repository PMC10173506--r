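# Levins' niche breadth and the generalist / common / specialist taxonomy.

#' Levins' niche breadth of one taxon
#'
#' B = 1 / sum(P^2) where P_i is the share of the taxon's abundance found in
#' sample i (the abundance vector normalized to sum 1). B ranges from 1
#' (confined to one sample) to the number of samples (perfectly even).
#'
#' @param x Non-negative per-sample abundances (counts or relative
#'   abundances; B is invariant to the overall scale).
#' @return The niche breadth, a scalar in `[1, length(x)]`.
#' @export
#' @examples
#' levins_b(c(1, 1, 1, 1))  # 4: even over four samples
#' levins_b(c(0, 5, 0))     # 1: confined to one sample
levins_b <- function(x) {
  if (any(x < 0)) abort("abundances must be non-negative")
  s <- sum(x)
  if (s == 0) abort("niche breadth is undefined for an all-zero abundance vector")
  p <- x / s
  1 / sum(p^2)
}

#' Classify niche breadth values into habitat categories
#'
#' Generalist if `B > upper`, specialist if `B < lower`, common otherwise
#' (both boundary values fall to common). The defaults 78 / 22 are the
#' cutoffs used on a 225-sample gradient; for other datasets derive
#' data-driven cutoffs with [suggest_thresholds()].
#'
#' @param b Numeric vector of niche breadths.
#' @param upper,lower Category cutoffs, `lower < upper`.
#' @return Character vector in `{generalist, common, specialist}`.
#' @export
classify_niche <- function(b, upper = 78, lower = 22) {
  if (lower >= upper) abort("`lower` must be below `upper`")
  dplyr::case_when(
    b > upper ~ "generalist",
    b < lower ~ "specialist",
    .default = "common"
  )
}

#' Data-driven niche-breadth cutoffs
#'
#' The generalist cutoff is the Tukey outlier fence Q3 + 1.5 IQR of the
#' B-value distribution (generalists are the upper outliers); the
#' specialist cutoff is the lower quartile Q1. Quantiles use the standard
#' linear-interpolation convention (R type 7).
#'
#' @param b Numeric vector of niche breadths (at least 8 values).
#' @param type Quantile algorithm passed to [stats::quantile()].
#' @return Named numeric vector `c(upper = , lower = )`.
#' @export
suggest_thresholds <- function(b, type = 7) {
  b <- b[!is.na(b)]
  if (length(b) < 8) abort("need at least 8 niche breadth values to derive thresholds")
  q <- stats::quantile(b, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) warn("degenerate B-value distribution: upper and lower thresholds coincide")
  c(upper = q[2] + 1.5 * iqr, lower = q[1])
}

#' Per-ASV niche profiles: breadth, prevalence, abundance, category
#'
#' Computes Levins' B for every ASV, applies the inclusion filters
#' (mean relative abundance and prevalence), and classifies included ASVs.
#' ASVs failing a filter get category `"excluded"`.
#'
#' By default B is computed from per-sample relative abundances (removing
#' sequencing-depth artifacts) re-normalized within each ASV; set
#' `use_relative = FALSE` to use raw counts.
#'
#' @param tbl Feature table tibble.
#' @param min_mean_rel_abund Inclusion floor on the mean (over samples) of
#'   within-sample relative abundance; inclusive (default 2e-5).
#' @param min_prevalence Inclusion floor on the number of samples with a
#'   positive count; inclusive (default 25).
#' @param upper,lower Fixed category cutoffs (defaults 78 / 22), or set
#'   `thresholds = "data"` to derive them from the included B values.
#' @param thresholds `"fixed"` (use `upper`/`lower`) or `"data"`
#'   ([suggest_thresholds()] on included ASVs).
#' @param use_relative Compute B from per-sample relative abundances
#'   (default) rather than raw counts.
#' @return A tibble with columns `asv_id`, `b`, `prevalence`,
#'   `mean_rel_abund`, `category`; the thresholds used are stored in the
#'   `thresholds` attribute.
#' @export
niche_profiles <- function(tbl,
                           min_mean_rel_abund = 2e-5,
                           min_prevalence = 25,
                           upper = 78, lower = 22,
                           thresholds = c("fixed", "data"),
                           use_relative = TRUE) {
  thresholds <- match.arg(thresholds)
  m <- ft_matrix(tbl)
  rel <- {
    tot <- colSums(m)
    tot[tot == 0] <- 1
    sweep(m, 2, tot, "/")
  }
  basis <- if (use_relative) rel else m
  prevalence <- rowSums(m > 0)
  mean_rel <- rowMeans(rel)
  b <- apply(basis, 1, function(x) if (sum(x) == 0) NA_real_ else levins_b(x))
  included <- mean_rel >= min_mean_rel_abund & prevalence >= min_prevalence
  thr <- c(upper = upper, lower = lower)
  if (thresholds == "data") thr <- suggest_thresholds(b[included])
  category <- rep("excluded", nrow(m))
  category[included] <- classify_niche(b[included], upper = thr["upper"], lower = thr["lower"])
  out <- tibble(
    asv_id = rownames(m),
    b = unname(b),
    prevalence = unname(prevalence),
    mean_rel_abund = unname(mean_rel),
    category = category
  )
  attr(out, "thresholds") <- thr
  out
}

#' Summarize niche categories: counts and community share
#'
#' For each category, the number of ASVs and the mean +/- sd (over samples)
#' of the category's summed relative abundance within each sample.
#'
#' @param profiles Output of [niche_profiles()].
#' @param tbl The feature table the profiles were computed from.
#' @return A tibble with columns `category`, `n_asvs`, `mean_share`,
#'   `sd_share`.
#' @export
category_summary <- function(profiles, tbl) {
  m <- ft_matrix(tbl)
  tot <- colSums(m)
  tot[tot == 0] <- 1
  rel <- sweep(m, 2, tot, "/")
  cats <- unique(profiles$category)
  purrr::map_dfr(cats, function(cat) {
    ids <- profiles$asv_id[profiles$category == cat]
    share <- colSums(rel[rownames(rel) %in% ids, , drop = FALSE])
    tibble(category = cat,
           n_asvs = length(ids),
           mean_share = mean(share),
           sd_share = stats::sd(share))
  }) |>
    dplyr::arrange(factor(.data$category,
                          levels = c("generalist", "common", "specialist", "excluded")))
}
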