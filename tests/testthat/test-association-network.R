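test_that("network_input_filter applies prevalence and peak-abundance rules", {
  # 40 samples of depth 1000 each
  n <- 40
  m <- rbind(
    rep(30, n),                       # prevalent and abundant: kept
    c(rep(3, 30), rep(0, 10)),        # prevalence 30, 0.3% peak: kept
    c(rep(0.4, n)),                   # 0.04% everywhere: dropped
    c(1000, rep(0, n - 1))            # abundant but prevalence 1: dropped
  )
  filler <- matrix(0, 1, n)
  filler[1, ] <- 1000 - colSums(m)
  ft <- make_ft(rbind(m, filler))
  kept <- network_input_filter(ft, min_prevalence = 25, min_max_rel_abund = 5e-4)
  expect_true(all(c("a01", "a02") %in% kept))
  expect_false(any(c("a03", "a04") %in% kept))
  expect_equal(network_input_filter(ft[0, ]), character(0))
})

test_that("spearman_all_pairs matches monotone closed forms", {
  base <- 1:12
  x <- rbind(a = base, b = 2 * base, c = rev(base))
  sp <- spearman_all_pairs(x)
  expect_equal(sp$rho["a", "b"], 1)
  expect_equal(sp$rho["a", "c"], -1)
  expect_equal(sp$p["a", "b"], 0)  # |rho| = 1
  expect_true(isSymmetric(sp$rho))
  expect_equal(unname(diag(sp$rho)), rep(1, 3))
})

test_that("spearman_all_pairs agrees with a rank-then-Pearson oracle to 1e-12", {
  set.seed(99)
  n_var <- 10
  for (rep in 1:5) {
    x <- matrix(rnorm(n_var * 25), nrow = n_var,
                dimnames = list(paste0("v", 1:n_var), NULL))
    sp <- spearman_all_pairs(x)
    for (i in 2:n_var) {
      for (j in 1:(i - 1)) {
        expect_equal(sp$rho[i, j], spearman_oracle(x[i, ], x[j, ]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("spearman p-values follow the two-sided t approximation", {
  set.seed(3)
  x <- matrix(rnorm(2 * 30), nrow = 2, dimnames = list(c("u", "v"), NULL))
  sp <- spearman_all_pairs(x)
  # oracle: Pearson test on midranks uses the same t transform
  ct <- cor.test(rank(x[1, ]), rank(x[2, ]), method = "pearson")
  expect_equal(sp$p["u", "v"], ct$p.value, tolerance = 1e-10)
  # the worked value: n = 30, rho = 0.5 gives p ~ 0.0049
  p_ref <- 2 * pt(-0.5 * sqrt(28 / 0.75), df = 28)
  expect_equal(p_ref, 0.0049, tolerance = 0.0002)
})

test_that("zero-variance and short pairs are flagged undefined", {
  x <- rbind(a = c(1, 2, 3, 4, 5), b = rep(2, 5), c = c(5, 1, 4, 2, 3))
  sp <- spearman_all_pairs(x, min_n = 4)
  expect_equal(attr(sp, "undefined"), "b")
  expect_true(is.na(sp$rho["a", "b"]))
  expect_false(is.na(sp$rho["a", "c"]))
  # pairwise-complete n accounting with missing values
  x2 <- rbind(a = c(1, 2, 3, 4, NA, 6, 7, 8, 9, 10, 11, 12),
              b = c(2, 1, 4, 3, 5, NA, 8, 7, 9, 12, 10, 11))
  sp2 <- spearman_all_pairs(x2)
  expect_equal(sp2$n["a", "b"], 10)
})

test_that("bh_fdr reproduces the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  set.seed(21)
  for (i in 1:10) {
    p <- runif(50)^2
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    # monotone nondecreasing in sorted-p order
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  # NAs preserved, m counts only tested pairs
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.01, 0.04)))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("build_network applies strict thresholds and positivity", {
  ids <- c("x", "y", "z")
  rho <- matrix(c(1, 0.6, -0.9, 0.6, 1, 0.5, -0.9, 0.5, 1), 3,
                dimnames = list(ids, ids))
  p <- matrix(1e-9, 3, 3, dimnames = list(ids, ids)); diag(p) <- 0
  q <- p
  meta <- tibble::tibble(id = ids, kind = "asv")
  net <- build_network(rho, p, q, meta)
  # only the rho = 0.6 pair passes: -0.9 fails positivity, 0.5 fails strict >
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$source, net$edges$target)), c("x", "y"))
  # isolated node z is dropped
  expect_false("z" %in% net$nodes$id)

  # allowing negatives keeps the magnitude-passing pair
  net2 <- build_network(rho, p, q, meta, positive_only = FALSE)
  expect_equal(nrow(net2$edges), 2)

  expect_error(build_network(matrix(c(1, 0.2, 0.8, 1), 2,
                                    dimnames = list(c("x", "y"), c("x", "y"))),
                             p[1:2, 1:2], q[1:2, 1:2], meta[1:2, ]),
               "symmetric")
})

test_that("edge sets grow monotonically as thresholds relax", {
  sim <- sim_small()
  tblf <- filter_low_count(sim$table)
  pr <- niche_profiles(tblf, thresholds = "data")
  strict <- build_conetwork(tblf, profiles = pr, rho_min = 0.7, alpha = 1e-4)
  loose <- build_conetwork(tblf, profiles = pr, rho_min = 0.5, alpha = 1e-3)
  key <- function(net) paste(net$edges$source, net$edges$target)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("within-block edge density exceeds between-block density", {
  sim <- sim_small()
  tblf <- filter_low_count(sim$table)
  pr <- niche_profiles(tblf, thresholds = "data")
  net <- build_conetwork(tblf, profiles = pr)
  truth <- sim$truth
  ed <- net$edges
  blk <- setNames(truth$module, truth$asv_id)
  bs <- blk[ed$source]; bt <- blk[ed$target]
  ok <- !is.na(bs) & !is.na(bt)
  n_block <- table(blk[names(blk) %in% net$nodes$id])
  within_edges <- sum(bs[ok] == bt[ok])
  between_edges <- sum(bs[ok] != bt[ok])
  within_pairs <- sum(n_block * (n_block - 1) / 2)
  between_pairs <- sum(n_block %o% n_block) / 2 - within_pairs
  expect_gt(within_edges / within_pairs, between_edges / between_pairs)
})

test_that("conetwork tidiers expose edges and summary", {
  sim <- sim_small()
  tblf <- filter_low_count(sim$table)
  pr <- niche_profiles(tblf, thresholds = "data")
  net <- build_conetwork(tblf, metadata = sim$metadata, profiles = pr)
  ed <- generics::tidy(net)
  expect_true(all(c("source", "target", "rho", "p", "q") %in% names(ed)))
  expect_true(all(ed$rho > 0.5 & ed$p < 0.001 & ed$q < 0.001))
  gl <- generics::glance(net)
  expect_equal(gl$n_edges, nrow(ed))
  expect_gt(gl$n_env_nodes, 0)
})
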