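make_panel_matrix <- function(n = 40, g = 8, seed = 60) {
  set.seed(seed)
  m <- matrix(rnorm(g * n, 5), g, n,
              dimnames = list(sprintf("p%02d", 1:g), sprintf("s%02d", 1:n)))
  m
}

test_that("rank-1 data collapses the score onto PC1", {
  s <- seq(-2, 2, length.out = 30)
  b <- c(1, -0.5, 2, 0.8)
  m <- 5 + outer(b, s) # exactly rank 1 after centering
  dimnames(m) <- list(paste0("g", 1:4), paste0("s", 1:30))
  sc <- compute_m6ascore(m, rownames(m), scale. = FALSE)
  expect_equal(sc$scores$pc2, rep(0, 30), tolerance = 1e-8)
  expect_equal(sc$scores$m6ascore, sc$scores$pc1, tolerance = 1e-8)
})

test_that("duplicating every sample leaves per-sample scores unchanged", {
  m <- make_panel_matrix()
  doubled <- cbind(m, m)
  colnames(doubled) <- c(colnames(m), paste0(colnames(m), "_dup"))
  a <- compute_m6ascore(m, rownames(m), scale. = FALSE)
  b <- compute_m6ascore(doubled, rownames(m), scale. = FALSE)
  expect_equal(b$scores$m6ascore[seq_len(ncol(m))], a$scores$m6ascore,
               tolerance = 1e-10)
})

test_that("m6ascore is invariant to gene and sample order and fully deterministic", {
  m <- make_panel_matrix()
  a <- compute_m6ascore(m, rownames(m))
  gperm <- sample(nrow(m)); sperm <- sample(ncol(m))
  b <- compute_m6ascore(m[gperm, sperm], rownames(m))
  expect_equal(b$scores$m6ascore[match(a$scores$sample, b$scores$sample)],
               a$scores$m6ascore, tolerance = 1e-10)
  # bit-identical rerun
  expect_identical(compute_m6ascore(m, rownames(m))$scores, a$scores)
  expect_identical(sum(a$var_explained) <= 1, TRUE)
  # loadings unit norm
  expect_equal(colSums(a$loadings^2), c(1, 1), ignore_attr = TRUE)
  expect_equal(a$scores$m6ascore, a$scores$pc1 + a$scores$pc2)
})

test_that("score input contracts are enforced", {
  m <- make_panel_matrix()
  expect_error(compute_m6ascore(m, c("p01", "p02")), ">= 3 panel genes")
  flat <- matrix(3, 4, 30, dimnames = list(paste0("g", 1:4), paste0("s", 1:30)))
  expect_error(compute_m6ascore(flat, rownames(flat)), "zero-variance")
})

test_that("validate_external reproduces training scores and degrades gracefully", {
  m <- make_panel_matrix(g = 10)
  model <- compute_m6ascore(m, rownames(m))
  back <- validate_external(model, m)
  expect_equal(back$scores$m6ascore, model$scores$m6ascore, tolerance = 1e-10)
  expect_equal(back$coverage, 1)
  # half the panel missing: still runs, logs coverage
  expect_message(half <- validate_external(model, m[1:5, ]), "coverage")
  expect_equal(half$coverage, 0.5)
  expect_length(half$missing_genes, 5)
  expect_error(validate_external(model, m[1:2, ]), "need >= 3")
})

test_that("external validation replicates the survival contrast direction", {
  co_train <- cached_cohort(seed = 42)
  co_ext <- cached_cohort(seed = 43)
  part <- truth_partition(co_train)
  deg <- suppressWarnings(moderated_anova(co_train$expr, part))
  pan <- suppressWarnings(cox_screen(co_train$expr, co_train$clinical,
                                     select_degs(deg)))
  model <- compute_m6ascore(co_train$expr, pan)
  tr_t <- truth_report(co_train); tr_e <- truth_report(co_ext)
  rho_train <- spearman_cor(model$scores$m6ascore,
                            tr_t$score[match(model$scores$sample, tr_t$sample_id)])$rho
  ext <- validate_external(model, co_ext$expr, co_ext$clinical)
  rho_ext <- spearman_cor(ext$scores$m6ascore,
                          tr_e$score[match(ext$scores$sample, tr_e$sample_id)])$rho
  # frozen loadings must transfer the score orientation to the new cohort
  expect_equal(sign(rho_ext), sign(rho_train))
  expect_gt(abs(rho_ext), 0.7)
  expect_lt(ext$contrast$p_naive, 0.05)
})

test_that("dichotomize_score respects minprop and matches the hazard direction", {
  co <- cached_cohort(seed = 42)
  part <- truth_partition(co)
  deg <- suppressWarnings(moderated_anova(co$expr, part))
  pan <- suppressWarnings(cox_screen(co$expr, co$clinical, select_degs(deg)))
  sc <- compute_m6ascore(co$expr, pan)
  d <- dichotomize_score(sc, co$clinical)
  n <- nrow(d$groups)
  expect_gte(min(table(d$groups$group)), ceiling(0.1 * n))
  expect_lt(d$p_naive, 0.05)
  # direction: group with higher median survival must be the low-hazard side
  tr <- truth_report(co)
  rho <- spearman_cor(d$groups$m6ascore,
                      tr$score[match(d$groups$sample, tr$sample_id)])$rho
  tmed <- stats::median(co$clinical$os_time)
  s_high <- km_surv_at(d$survival$curves$high, tmed)
  s_low <- km_surv_at(d$survival$curves$low, tmed)
  if (rho > 0) expect_lt(s_high, s_low) else expect_gt(s_high, s_low)
})

test_that("independent prognostic analysis keeps the score term significant", {
  co <- cached_cohort(seed = 42)
  part <- truth_partition(co)
  deg <- suppressWarnings(moderated_anova(co$expr, part))
  pan <- suppressWarnings(cox_screen(co$expr, co$clinical, select_degs(deg)))
  sc <- compute_m6ascore(co$expr, pan)
  ipa <- independent_prognostic_analysis(sc, co$clinical)
  expect_equal(ipa$univariate$term, "m6ascore")
  expect_setequal(ipa$multivariate$term,
                  c("m6ascore", "age", "gender", "grade", "stage"))
  expect_lt(ipa$univariate$p, 0.05)
  expect_lt(ipa$multivariate$p[ipa$multivariate$term == "m6ascore"], 0.05)
  # HR is per unit of score: exp(beta) with no internal rescaling
  expect_equal(ipa$univariate$HR, exp(ipa$univariate$beta))
})

test_that("tmb_integration reports counts, correlation and the 4-way contrast", {
  co <- cached_cohort(seed = 42)
  part <- truth_partition(co)
  deg <- suppressWarnings(moderated_anova(co$expr, part))
  pan <- suppressWarnings(cox_screen(co$expr, co$clinical, select_degs(deg)))
  sc <- compute_m6ascore(co$expr, pan)
  d <- dichotomize_score(sc, co$clinical)
  tmb <- tmb_integration(d, co$mutations, co$clinical, per_mb = TRUE)
  expect_true(all(tmb$tmb$tmb_count >= 0))
  expect_equal(tmb$tmb$tmb_per_mb, tmb$tmb$tmb_count / 38)
  expect_length(tmb$joint_survival$curves, 4)
  expect_equal(tmb$joint_survival$global$df, 3)
  # burden is planted against the latent score, so its correlation with the
  # m6ascore carries the opposite sign of the score-truth correlation
  tr <- truth_report(co)
  rho_truth <- spearman_cor(d$groups$m6ascore,
                            tr$score[match(d$groups$sample, tr$sample_id)])$rho
  expect_equal(sign(tmb$correlation$rho), -sign(rho_truth))
})

test_that("regulator_network classifies planted risk and protective genes", {
  set.seed(61)
  n <- 200
  reg <- load_regulator_registry()
  risk <- rnorm(n)
  m <- matrix(rnorm(22 * n, 5), 22, n,
              dimnames = list(reg$symbol, sprintf("s%03d", 1:n)))
  m["IGF2BP2", ] <- 5 + risk + rnorm(n, 0, 0.3)   # tumorigenic analog
  m["ALKBH5", ] <- 5 - risk + rnorm(n, 0, 0.3)    # tumor-suppressing analog
  clin <- data.frame(sample_id = colnames(m),
                     os_time = rexp(n, 0.002 * exp(0.8 * risk)),
                     os_event = rbinom(n, 1, 0.8))
  clin$os_time <- pmax(clin$os_time, 1)
  net <- regulator_network(m, clin)
  nodes <- stats::setNames(net$nodes$prognosis, net$nodes$symbol)
  expect_equal(unname(nodes["IGF2BP2"]), "risk")
  expect_equal(unname(nodes["ALKBH5"]), "protective")
  expect_lte(nrow(net$edges), 22 * 21 / 2)
  # the two planted genes move oppositely: their edge (if kept) is negative
  e <- net$edges
  ab <- e[(e$gene_a == "IGF2BP2" & e$gene_b == "ALKBH5") |
            (e$gene_b == "IGF2BP2" & e$gene_a == "ALKBH5"), ]
  if (nrow(ab)) expect_lt(ab$rho, 0)
})

test_that("co-regulated regulators form positive edges on planted cohorts", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  net <- regulator_network(co$expr, co$clinical)
  expect_gt(mean(net$edges$rho > 0), 0.95)
  absent <- regulator_network(co$expr[-match("WTAP", rownames(co$expr)), ],
                              co$clinical)
  expect_equal(absent$nodes$prognosis[absent$nodes$symbol == "WTAP"], "absent")
  expect_false(any(absent$edges$gene_a == "WTAP" | absent$edges$gene_b == "WTAP"))
})

test_that("attribute_flow_table keeps one row per sample with conserved margins", {
  ids <- sprintf("s%02d", 1:30)
  m6a <- stats::setNames(sample(c("A", "B", "C"), 30, TRUE), ids)
  gcl <- stats::setNames(sample(c("A", "B"), 30, TRUE), ids)
  grp <- stats::setNames(sample(c("high", "low"), 30, TRUE), ids)
  fl <- attribute_flow_table(m6a, gcl, grp)
  expect_equal(nrow(fl), 30)
  ct <- attr(fl, "crosstab")
  expect_equal(as.vector(apply(ct, 1, sum)), as.vector(table(m6a)))
  expect_error(attribute_flow_table(m6a[1:20], gcl, grp), "different sample sets")
})
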