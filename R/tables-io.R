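# Reading, writing, and basic transforms of ASV count tables.
#
# The canonical on-disk form is TSV with a header row and the identifier in
# the first column. In memory a feature table is a wide tibble: first column
# `asv_id`, one numeric column per sample.

#' Read an ASV-by-sample count table from TSV
#'
#' @param path Path to a tab-separated file with a header row; the first
#'   column holds identifiers.
#' @param orientation Either `"asv_rows"` (rows are ASVs, columns are
#'   samples; the canonical layout) or `"sample_rows"` (transposed input,
#'   e.g. exported from ordination tools).
#'
#' @return A tibble with column `asv_id` followed by one integer column per
#'   sample. Duplicate identifiers, negative counts, and malformed numeric
#'   cells are rejected with informative errors.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("asv_id\ts1\ts2", "a\t1\t2", "b\t0\t5"), tf)
#' read_feature_table(tf)
read_feature_table <- function(path, orientation = c("asv_rows", "sample_rows")) {
  orientation <- match.arg(orientation)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) {
    abort(sprintf("'%s': expected an id column plus at least one data column", path))
  }
  ids <- raw[[1]]
  num <- raw[, -1, drop = FALSE]
  for (j in seq_along(num)) {
    parsed <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(parsed) & !is.na(num[[j]]))
    if (length(bad) > 0) {
      abort(sprintf(
        "'%s': malformed numeric cell '%s' at row '%s', column '%s'",
        path, num[[j]][bad[1]], ids[bad[1]], names(num)[j]))
    }
    num[[j]] <- parsed
  }
  tbl <- tibble(asv_id = ids)
  tbl <- dplyr::bind_cols(tbl, num)
  if (orientation == "sample_rows") {
    m <- t(ft_matrix(dplyr::rename(tbl, sample_id = "asv_id")))
    tbl <- ft_tibble(m)
  }
  validate_feature_table(tbl, call_name = path)
  tbl
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]; the round trip preserves counts exactly.
#'
#' @param tbl Feature table tibble (`asv_id` + sample columns).
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  validate_feature_table(tbl)
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Read per-ASV taxonomy (id plus rank columns) from TSV
#'
#' @param path TSV with `asv_id` first, then rank columns (domain ... genus).
#' @return A tibble, one row per ASV.
#' @export
read_taxonomy <- function(path) {
  tx <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  names(tx)[1] <- "asv_id"
  if (anyDuplicated(tx$asv_id) > 0) {
    abort(sprintf("'%s': duplicate ASV ids in taxonomy", path))
  }
  tx
}

#' Read per-sample metadata (environmental covariates) from TSV
#'
#' The first column is the sample id; remaining columns are covariates.
#' Numeric-looking columns are parsed as numeric, others (e.g. the elevation
#' stratum) kept as character.
#'
#' @param path TSV path.
#' @return A tibble, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  md <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                        show_col_types = FALSE)
  names(md)[1] <- "sample_id"
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id) > 0) {
    abort(sprintf("'%s': duplicate sample ids in metadata", path))
  }
  md
}

#' Remove low-count ASVs
#'
#' Drops ASVs whose total count across all samples falls below `min_total`.
#' The default of 4 removes singletons, doubletons, and tripletons, the
#' conventional guard against sequencing-error ASVs.
#'
#' @param tbl Feature table tibble.
#' @param min_total Minimum summed count across samples (default 4).
#' @return Filtered feature table tibble (possibly with zero rows).
#' @export
filter_low_count <- function(tbl, min_total = 4) {
  stopifnot(min_total >= 1)
  m <- ft_matrix(tbl)
  keep <- rowSums(m) >= min_total
  tbl[keep, , drop = FALSE]
}

#' Per-sample relative abundances
#'
#' Divides each sample column by its total so nonzero columns sum to 1.
#' All-zero samples stay zero and are reported in the `zero_samples`
#' attribute (with a warning).
#'
#' @param tbl Feature table tibble.
#' @return A tibble of the same shape holding proportions.
#' @export
relative_abundance <- function(tbl) {
  m <- ft_matrix(tbl)
  totals <- colSums(m)
  zero <- totals == 0
  totals[zero] <- 1
  props <- sweep(m, 2, totals, "/")
  out <- ft_tibble(props)
  if (any(zero)) {
    warn(sprintf("%d all-zero sample(s) left as zeros: %s",
                 sum(zero), paste(colnames(m)[zero], collapse = ", ")))
    attr(out, "zero_samples") <- colnames(m)[zero]
  }
  out
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's counts without replacement to `depth` reads
#' (via \code{vegan::rrarefy}). Samples whose total is below the target are
#' dropped with a warning rather than upsampled.
#'
#' @param tbl Feature table tibble.
#' @param depth Integer target depth, or `"min"` for the smallest sample
#'   total.
#' @param seed Integer seed fixing the draw; same seed, same output.
#' @return Rarefied feature table; every retained sample column sums to
#'   `depth`.
#' @export
rarefy_counts <- function(tbl, depth = "min", seed = 1) {
  m <- ft_matrix(tbl)
  totals <- colSums(m)
  if (identical(depth, "min")) depth <- min(totals)
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) abort("rarefaction depth must be a positive integer")
  drop <- totals < depth
  if (any(drop)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(drop), depth, paste(colnames(m)[drop], collapse = ", ")))
    m <- m[, !drop, drop = FALSE]
  }
  if (ncol(m) == 0) abort("no samples at or above the rarefaction depth")
  if (all(m == round(m))) storage.mode(m) <- "integer"
  # vegan heuristically warns when the smallest count looks large; counts
  # here are already validated as non-negative integers
  rar <- with_seed_(seed, withCallingHandlers(
    t(vegan::rrarefy(t(m), sample = depth)),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  storage.mode(rar) <- "double"
  ft_tibble(rar)
}

#' Shannon diversity per sample
#'
#' H = -sum(p log p) over an individual sample's nonzero proportions,
#' natural logarithm (computed with \code{vegan::diversity}).
#'
#' @param tbl Feature table tibble; every sample must have a positive total.
#' @return Tibble with columns `sample_id` and `shannon`.
#' @export
shannon_diversity <- function(tbl) {
  m <- ft_matrix(tbl)
  totals <- colSums(m)
  if (any(totals == 0)) {
    abort(sprintf("cannot compute Shannon diversity for all-zero sample(s): %s",
                  paste(colnames(m)[totals == 0], collapse = ", ")))
  }
  h <- vegan::diversity(t(m), index = "shannon")
  tibble(sample_id = colnames(m), shannon = unname(h))
}
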