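# Helper: two crisp Gaussian blobs as a genes x samples matrix.
make_blobs <- function(n_per = 15, n_genes = 6, gap = 10, sd = 0.3, seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n_genes * n_per, 0, sd), n_genes),
             matrix(rnorm(n_genes * n_per, gap, sd), n_genes))
  dimnames(m) <- list(paste0("g", seq_len(n_genes)),
                      paste0("s", seq_len(2 * n_per)))
  m
}

test_that("well-separated blobs give a 0/1 consensus matrix at k = 2", {
  m <- make_blobs()
  cc <- consensus_cluster(m, k_range = 2:3, n_resamples = 80, seed = 3)
  M <- cc$consensus[["2"]]
  truth <- rep(c(1, 2), each = 15)
  same <- outer(truth, truth, "==")
  expect_true(all(M[same] == 1))
  expect_true(all(M[!same] == 0))
})

test_that("an identical duplicated sample always co-clusters with its twin", {
  m <- make_blobs(n_per = 10)
  m <- cbind(m, twin = m[, 1]) # exact duplicate of sample 1
  colnames(m)[ncol(m)] <- "twin"
  cc <- consensus_cluster(m, k_range = 2:4, n_resamples = 80, seed = 4)
  for (k in names(cc$consensus))
    expect_equal(cc$consensus[[k]]["s1", "twin"], 1)
})

test_that("consensus matrices satisfy their structural invariants", {
  co <- cached_cohort(n_samples = 60, seed = 11)
  reg <- load_regulator_registry()
  cc <- consensus_cluster(co$expr[reg$symbol, ], k_range = 2:4,
                          n_resamples = 60, seed = 5)
  for (M in cc$consensus) {
    expect_true(all(M >= 0 & M <= 1))
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 1))
  }
  # rerun with the same seed is identical
  cc2 <- consensus_cluster(co$expr[reg$symbol, ], k_range = 2:4,
                           n_resamples = 60, seed = 5)
  expect_identical(cc$consensus, cc2$consensus)
  expect_identical(cc$partition, cc2$partition)
  # partition has exactly selected_k non-empty clusters
  expect_equal(length(unique(cc$partition)), cc$selected_k)
})

test_that("more resamples shrink the Monte-Carlo variance of consensus entries", {
  # a weakly structured cohort, so consensus entries are genuinely stochastic
  # (on crisply planted data they are exactly 0/1 at any resample depth)
  co <- cached_cohort(n_samples = 40, seed = 13, cluster_shift = 0.5,
                      key = "weak40")
  reg <- load_regulator_registry()
  feat <- co$expr[reg$symbol, ]
  m50 <- lapply(c(21, 22), function(s) suppressWarnings(
    consensus_cluster(feat, k_range = 3, n_resamples = 50, seed = s))$consensus[["3"]])
  m400 <- lapply(c(23, 24), function(s) suppressWarnings(
    consensus_cluster(feat, k_range = 3, n_resamples = 400, seed = s))$consensus[["3"]])
  d50 <- mean(abs(m50[[1]] - m50[[2]]))
  d400 <- mean(abs(m400[[1]] - m400[[2]]))
  expect_lt(d400, d50)
})

test_that("planted 3-cluster cohort is recovered with the right k", {
  co <- cached_cohort(seed = 42) # defaults: n = 150, shift 2 sigma
  reg <- load_regulator_registry()
  cc <- consensus_cluster(co$expr[reg$symbol, ], n_resamples = 250, seed = 6)
  expect_equal(cc$selected_k, 3L)
  truth <- truth_partition(co)
  expect_gte(adjusted_rand_index(cc$partition, truth[names(cc$partition)]), 0.9)
})

test_that("cdf_delta_area handles degenerate and perfect structure", {
  ones <- matrix(1, 10, 10)
  ms <- list("2" = ones, "3" = ones, "4" = ones)
  sel <- cdf_delta_area(ms)
  expect_true(all(sel$delta_area[c("3", "4")] == 0))
  expect_warning(cdf_delta_area(list("2" = ones)), "single k")
  # CDF is a proper CDF: nondecreasing from 0 to 1
  co <- cached_cohort(n_samples = 60, seed = 11)
  reg <- load_regulator_registry()
  cc <- consensus_cluster(co$expr[reg$symbol, ], k_range = 2:4,
                          n_resamples = 60, seed = 5)
  F <- cc$cdf[["3"]]
  grid <- seq(0, 1, length.out = 101)
  expect_false(is.unsorted(F(grid)))
  expect_equal(F(1), 1)
})

test_that("errors are raised for bad k ranges and undersampled pairs", {
  m <- make_blobs(n_per = 5)
  expect_error(consensus_cluster(m, k_range = c(2, 10), n_resamples = 10), "k_range")
  expect_error(consensus_cluster(m, k_range = 2, n_resamples = 1,
                                 subsample_fraction = 0.3),
               "co-sampled")
})

test_that("cluster_expression_summary orders planted clusters and reports skips", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  part <- truth_partition(co)
  reg <- load_regulator_registry()
  out <- cluster_expression_summary(co$expr, part, c(reg$symbol, "MISSING_GENE"))
  expect_equal(attr(out, "skipped"), "MISSING_GENE")
  expect_equal(nrow(out), 22 * 3) # genes found x clusters
  med <- reshape(out[, c("gene", "cluster", "median")], idvar = "gene",
                 timevar = "cluster", direction = "wide")
  # B analog (all-high) beats A analog (all-low) for every regulator
  expect_true(all(med$median.B > med$median.A))
  expect_true(all(out$p < 0.01)) # 2 sigma shifts: all regulators significant
})
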