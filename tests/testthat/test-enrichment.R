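test_that("ssgsea_score matches the brute-force running sum on small universes", {
  set.seed(20)
  for (rep in 1:20) {
    N <- sample(8:20, 1)
    genes <- sprintf("g%02d", seq_len(N))
    x <- matrix(rnorm(N * 3, 5), N, 3, dimnames = list(genes, c("a", "b", "c")))
    m <- sample(2:min(6, N - 2), 1)
    set <- sample(genes, m)
    for (alpha in c(0, 0.25, 1)) {
      sc <- ssgsea_score(x, list(s = set), alpha = alpha, min_overlap = 2,
                         normalize = FALSE)
      for (j in colnames(x))
        expect_equal(sc[j, "s"], oracle_ssgsea(x[, j], set, alpha),
                     tolerance = 1e-9)
    }
  }
})

test_that("set genes ranked top score higher than ranked bottom", {
  genes <- sprintf("g%02d", 1:10)
  a <- stats::setNames(c(10:6, 5:1), genes)      # set genes g01..g03 on top
  b <- stats::setNames(c(1:5, 6:10), genes)      # and at the bottom in b
  x <- cbind(A = a, B = b)
  sc <- ssgsea_score(x, list(s = genes[1:3]), min_overlap = 2, normalize = FALSE)
  expect_gt(sc["A", "s"], sc["B", "s"])
})

test_that("scores are invariant under monotone per-sample transforms", {
  set.seed(21)
  x <- matrix(rexp(40 * 4) + 0.1, 40, 4,
              dimnames = list(sprintf("g%02d", 1:40), paste0("s", 1:4)))
  sets <- list(u = rownames(x)[1:8], v = rownames(x)[9:20])
  base <- ssgsea_score(x, sets, normalize = FALSE)
  y <- x
  y[, 1] <- exp(y[, 1]); y[, 3] <- y[, 3]^3 # strictly increasing maps
  expect_equal(ssgsea_score(y, sets, normalize = FALSE), base,
               ignore_attr = TRUE)
})

test_that("overlap filtering drops small sets and degenerate samples error", {
  set.seed(22)
  x <- matrix(rnorm(30 * 3, 5), 30, 3,
              dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:3)))
  expect_warning(
    sc <- ssgsea_score(x, list(big = rownames(x)[1:10], tiny = c("g01", "nope")),
                       min_overlap = 5),
    "tiny")
  expect_equal(colnames(sc), "big")
  expect_equal(attr(sc, "dropped"), "tiny")
  flat <- x; flat[, 2] <- 7
  expect_error(ssgsea_score(flat, list(big = rownames(x)[1:10])), "all-tied")
})

test_that("estimate_scores additivity is exact and rank-invariant", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  est <- estimate_scores(co$expr, co$gene_sets$estimate$ESTIMATE_stromal,
                         co$gene_sets$estimate$ESTIMATE_immune)
  expect_identical(est$estimate_score, est$stromal_score + est$immune_score)
  # adding a constant to every gene of one sample changes nothing
  shifted <- unclass(co$expr)[, ]
  shifted[, 3] <- shifted[, 3] + 5
  est2 <- estimate_scores(shifted, co$gene_sets$estimate$ESTIMATE_stromal,
                          co$gene_sets$estimate$ESTIMATE_immune)
  expect_equal(est2, est)
  # stromal-analog genes planted high in cluster B
  part <- truth_partition(co)[est$sample]
  med <- vapply(split(est$stromal_score, part), stats::median, numeric(1))
  expect_equal(names(which.max(med)), "B")
})

test_that("immune landscape table flags planted signatures with correct stars", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  sc <- ssgsea_score(co$expr, co$gene_sets$immune)
  tab <- immune_landscape_table(sc, truth_partition(co))
  expect_equal(nrow(tab), 23L)
  th2 <- tab[tab$signature == "Th2_cell", ]
  expect_lt(th2$p_adj, 0.05)
  expect_equal(names(which.max(unlist(th2[paste0("median_", c("A", "B", "C"))]))),
               "median_B")
  expect_identical(tab$stars, significance_stars(tab$p_adj))
  expect_identical(significance_stars(c(0.04, 0.009, 0.0009, 0.9)),
                   c("*", "**", "***", ""))
})

test_that("label permutation removes landscape significance in most reps", {
  # spec rate >= 95%; assert >= 80% to leave ~3 MC sds of slack at 30 reps
  co <- cached_cohort(n_samples = 120, seed = 5)
  sc <- ssgsea_score(co$expr, co$gene_sets$immune)
  set.seed(30)
  clean <- replicate(30, {
    perm <- stats::setNames(sample(co$truth$cluster), co$truth$sample_id)
    all(immune_landscape_table(sc, perm)$p_adj >= 0.05)
  })
  expect_gte(mean(clean), 0.8)
})

test_that("pathway activity recovers the planted FoxO-like contrast", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  pw <- pathway_activity(co$expr, co$gene_sets$pathway)
  expect_equal(ncol(pw), length(co$gene_sets$pathway))
  contrast <- moderated_anova(t(pw), truth_partition(co))
  expect_lt(contrast$p_adj[contrast$gene == "FoxO_like"], 0.05)
  expect_lt(contrast$p_adj[contrast$gene == "ErbB_like"], 0.05)
})

test_that("null pathway sets are null-calibrated on null cohorts", {
  ps <- unlist(lapply(1:8, function(s) {
    co <- simulate_cohort(sim_config(n_samples = 50, seed = 7000 + s,
                                     cluster_shift = 0, signal_shift = 0,
                                     set_shift = 0, hazard_beta = 0,
                                     tmb_rho = 0))
    pw <- pathway_activity(co$expr, co$gene_sets$pathway)
    moderated_anova(t(pw), truth_partition(co))$p
  }))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
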