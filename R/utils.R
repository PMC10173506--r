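# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed_ <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Coerce a wide feature table (first column = ASV id, remaining columns =
# samples) to a named count matrix. Validates shape, not count values.
ft_matrix <- function(tbl) {
  stopifnot(is.data.frame(tbl), ncol(tbl) >= 2)
  ids <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (nrow(m) == 0) {
    m <- matrix(numeric(0), 0, ncol(tbl) - 1,
                dimnames = list(NULL, names(tbl)[-1]))
  }
  if (!is.numeric(m)) {
    abort("feature table sample columns must all be numeric")
  }
  rownames(m) <- ids
  m
}

# Back to the tibble representation used by every user-facing function.
ft_tibble <- function(m, id_col = "asv_id") {
  out <- as_tibble(m, rownames = id_col)
  out
}

# Full invariant check used by readers and the simulator.
validate_feature_table <- function(tbl, call_name = "feature table") {
  m <- ft_matrix(tbl)
  ids <- rownames(m)
  if (anyDuplicated(ids) > 0) {
    abort(sprintf("%s: duplicate ASV ids (e.g. '%s')",
                  call_name, ids[duplicated(ids)][1]))
  }
  if (anyDuplicated(colnames(m)) > 0) {
    abort(sprintf("%s: duplicate sample ids (e.g. '%s')",
                  call_name, colnames(m)[duplicated(colnames(m))][1]))
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(sprintf("%s: missing count at ASV '%s', sample '%s'",
                  call_name, ids[idx[1]], colnames(m)[idx[2]]))
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("%s: negative count at ASV '%s', sample '%s'",
                  call_name, ids[idx[1]], colnames(m)[idx[2]]))
  }
  invisible(tbl)
}

# Population standard deviation (denominator n), used by Zi and network
# heterogeneity, which follow the Guimera-Amaral / NetworkAnalyzer convention.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

# Round half away from zero to `digits` decimals (display convention for
# percentage tables; R's round() would round half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
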