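# Synthetic cohorts with the statistical structure the analysis assumes:
# planted regulator-driven sample clusters, a latent per-sample risk score
# that drives both survival and a block of signal genes, MAF-like mutation
# tables whose burden is anti-correlated with the score, CNV calls for the
# regulator panel, and signature-set fixtures (23 immune-cell sets,
# ESTIMATE stromal/immune sets, pathway sets) planted into the expression.

#' Simulation configuration
#'
#' Defaults are the stated world of the analysis: n = 150 samples in three
#' clusters with the 30/42/105 composition of the motivating cohort, the
#' 22-gene regulator panel shifted by 2 within-gene standard deviations
#' between the extreme clusters, a latent risk score with Cox log-hazard
#' 0.7 per unit, ~40% censoring, and mutation burden anti-correlated with
#' the score.
#'
#' Cluster semantics mirror the biology: cluster A = all regulators low,
#' best prognosis; cluster B = all regulators high, worst prognosis;
#' cluster C intermediate. The latent score is risk-oriented
#' (A mean -1, C mean 0, B mean +1, plus N(0, 0.5) noise) and enters the
#' hazard as `h0 * exp(hazard_beta * score)`.
#'
#' @param n_samples cohort size.
#' @param n_genes total gene universe (must fit the named blocks plus filler).
#' @param n_regulators number of regulator-analog genes (the 22 registry
#'   symbols are used when 22).
#' @param n_clusters number of planted clusters (>= 2).
#' @param cluster_props cluster mixing proportions (sum to 1); default
#'   30/42/105 out of 177.
#' @param cluster_shift regulator mean shift in log2 units per unit of
#'   cluster center (centers span -1..+1, so the extreme-cluster difference
#'   is `2 * cluster_shift` sd at `sigma = 1`).
#' @param sigma residual sd of log2 expression.
#' @param n_signal_genes genes whose mean follows the latent score (the true
#'   DEG block feeding the prognostic panel).
#' @param signal_shift log2 shift per unit latent score for signal genes.
#' @param set_shift log2 shift per unit cluster center for planted
#'   signature-set genes (immune/ESTIMATE/pathway fixtures). Default 1:
#'   half the regulator shift, reflecting that pathway-level co-regulation
#'   moves member genes by fractions of the within-gene sd while still
#'   giving set-level enrichment contrasts overwhelming power.
#' @param hazard_beta Cox log-hazard per unit latent score.
#' @param baseline_hazard exponential baseline hazard (per day); default
#'   log(2)/500, i.e. 500-day median survival at score 0.
#' @param censor_rate target fraction censored, strictly inside (0, 1).
#' @param tmb_rho slope of log mutation-count mean per unit score; negative
#'   plants the score/TMB anti-correlation.
#' @param tmb_mean expected non-silent mutation count at score 0.
#' @param seed master seed; fully determines the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 150, n_genes = 2000, n_regulators = 22,
                       n_clusters = 3, cluster_props = c(30, 42, 105) / 177,
                       cluster_shift = 2, sigma = 1,
                       n_signal_genes = 300, signal_shift = 1, set_shift = 1,
                       hazard_beta = 0.7, baseline_hazard = log(2) / 500,
                       censor_rate = 0.4, tmb_rho = -0.4, tmb_mean = 30,
                       seed = 1) {
  if (n_clusters < 2) .stopf("n_clusters must be >= 2")
  if (length(cluster_props) != n_clusters) {
    if (length(cluster_props) == 3 && n_clusters != 3)
      cluster_props <- rep(1 / n_clusters, n_clusters)
    else .stopf("cluster_props must have length n_clusters")
  }
  if (abs(sum(cluster_props) - 1) > 1e-8) .stopf("cluster_props must sum to 1")
  if (censor_rate <= 0 || censor_rate >= 1)
    .stopf("censor_rate must be strictly inside (0, 1)")
  cfg <- list(n_samples = n_samples, n_genes = n_genes,
              n_regulators = n_regulators, n_clusters = n_clusters,
              cluster_props = cluster_props, cluster_shift = cluster_shift,
              sigma = sigma, n_signal_genes = n_signal_genes,
              signal_shift = signal_shift, set_shift = set_shift,
              hazard_beta = hazard_beta,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              tmb_rho = tmb_rho, tmb_mean = tmb_mean, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Cluster risk centers: equally spaced in [-1, 1]; for the default k = 3
# this is A = -1, B = +1, C = 0 after the A/B/C naming below.
.cluster_centers <- function(k) {
  cen <- seq(-1, 1, length.out = k)
  # name so that the last-lettered clusters are intermediate and B is the
  # high-risk pole, matching the A-low / B-high / C-intermediate pattern.
  if (k == 3) stats::setNames(c(-1, 1, 0), c("A", "B", "C"))
  else stats::setNames(cen, LETTERS[seq_len(k)])
}

#' Signature-set fixtures for a simulated cohort
#'
#' Allocates disjoint gene blocks for 23 immune-cell sets (15 genes each),
#' one ESTIMATE stromal and one ESTIMATE immune set (30 genes each), and 12
#' pathway sets (20 genes each). Each set carries a planted direction:
#' +1 = elevated in the high-risk cluster (B analog), -1 = depressed there,
#' 0 = null. Th2/activated-NK/mast-cell analogs and the stromal + immune
#' sets are planted up in B; the CD56dim-NK analog down in B; the FoxO-like
#' pathway up in B and the ErbB-like pathway down; all other sets are null.
#'
#' @param cfg a [sim_config()].
#' @return list of `gene_sets` collections: `immune` (23 sets), `estimate`
#'   (2 sets), `pathway` (12 sets); each set has a `direction` attribute.
#' @export
make_signature_fixtures <- function(cfg) {
  immune_names <- c(
    "Activated_CD4_T_cell", "Activated_CD8_T_cell", "Activated_dendritic_cell",
    "Activated_NK_cell", "CD56bright_NK_cell", "CD56dim_NK_cell",
    "Central_memory_CD4_T_cell", "Central_memory_CD8_T_cell",
    "Effector_memory_CD4_T_cell", "Effector_memory_CD8_T_cell",
    "Eosinophil", "Gamma_delta_T_cell", "Immature_B_cell",
    "Immature_dendritic_cell", "Macrophage", "Mast_cell", "MDSC",
    "Memory_B_cell", "Monocyte", "Neutrophil", "Plasmacytoid_dendritic_cell",
    "Regulatory_T_cell", "Th2_cell")
  stopifnot(length(immune_names) == 23)
  pathway_names <- c("FoxO_like", "ErbB_like", "Cell_cycle_like", "P53_like",
                     "Wnt_like", "MAPK_like", "Apoptosis_like", "Adhesion_like",
                     "Metabolism_like", "Hedgehog_like", "Notch_like", "TGFb_like")
  sizes <- c(rep(15, 23), 30, 30, rep(20, length(pathway_names)))
  total <- sum(sizes)
  reserved <- cfg$n_regulators + 3 + cfg$n_signal_genes # regulators + checkpoints + DEGs
  if (reserved + total > cfg$n_genes)
    .stopf("gene-set allocation (%d) exceeds gene universe (%d free of %d)",
           total, cfg$n_genes - reserved, cfg$n_genes)
  all_names <- c(immune_names, "ESTIMATE_stromal", "ESTIMATE_immune", pathway_names)
  dirs <- stats::setNames(rep(0, length(all_names)), all_names)
  dirs[c("Th2_cell", "Activated_NK_cell", "Mast_cell",
         "ESTIMATE_stromal", "ESTIMATE_immune", "FoxO_like")] <- 1
  dirs[c("CD56dim_NK_cell", "ErbB_like")] <- -1
  sets <- vector("list", length(all_names))
  names(sets) <- all_names
  offset <- 0
  for (i in seq_along(all_names)) {
    idx <- offset + seq_len(sizes[i])
    tag <- toupper(gsub("[^A-Za-z0-9]", "", substr(all_names[i], 1, 8)))
    sets[[i]] <- structure(sprintf("SIG_%s_%03d", tag, idx),
                           direction = unname(dirs[i]))
    offset <- offset + sizes[i]
  }
  list(
    immune = structure(sets[immune_names], class = "gene_sets",
                       category = "immune_cell"),
    estimate = structure(sets[c("ESTIMATE_stromal", "ESTIMATE_immune")],
                         class = "gene_sets", category = "estimate"),
    pathway = structure(sets[pathway_names], class = "gene_sets",
                        category = "pathway")
  )
}

# Solve for the exponential censoring rate c so that the expected censored
# fraction, averaged over the per-sample event rates, hits the target:
# P(censored | rate lambda_i) = c / (c + lambda_i).
.calibrate_censoring <- function(rates, target) {
  f <- function(lc) mean(exp(lc) / (exp(lc) + rates)) - target
  lo <- log(min(rates)) - 15; hi <- log(max(rates)) + 15
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Simulate a cohort with known ground truth
#'
#' Generates, from one master seed, an expression matrix (log2 scale) with
#' planted regulator clusters and score-driven signal genes, clinical
#' survival data with exponential event and censoring times, a MAF-like
#' mutation table, regulator CNV calls, and the signature fixtures of
#' [make_signature_fixtures()]. Each component draws from its own derived
#' seed stream so sub-tables are independently reproducible.
#'
#' @param cfg a [sim_config()].
#' @return a `synthetic_cohort` list: `expr` (an [expr_matrix()], unit
#'   `LOG2_TPM`), `clinical`, `mutations`, `cnv`, `gene_sets`, `truth`
#'   (sample_id, cluster, score), and `config`.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_samples
  k <- cfg$n_clusters
  sample_ids <- sprintf("S%04d", seq_len(n))
  centers <- .cluster_centers(k)

  # --- cluster labels (largest-remainder apportionment, then shuffled) ----
  set.seed(m6a_seed(cfg$seed, 1L))
  counts <- floor(cfg$cluster_props * n)
  rem <- cfg$cluster_props * n - counts
  short <- n - sum(counts)
  if (short > 0) counts[order(rem, decreasing = TRUE)[seq_len(short)]] <-
      counts[order(rem, decreasing = TRUE)[seq_len(short)]] + 1
  cluster <- sample(rep(names(centers), counts))
  names(cluster) <- sample_ids

  # --- latent risk score -------------------------------------------------
  set.seed(m6a_seed(cfg$seed, 2L))
  score <- centers[cluster] + stats::rnorm(n, 0, 0.5)
  names(score) <- sample_ids

  # --- gene universe -----------------------------------------------------
  registry <- load_regulator_registry()
  reg_genes <- if (cfg$n_regulators == 22) registry$symbol
               else sprintf("REG%03d", seq_len(cfg$n_regulators))
  checkpoint_genes <- c("PDCD1", "CD274", "CTLA4")
  sig_genes <- sprintf("DEG%04d", seq_len(cfg$n_signal_genes))
  fixtures <- make_signature_fixtures(cfg)
  set_genes <- unique(unlist(lapply(fixtures, function(col) unlist(col, use.names = FALSE))))
  n_named <- length(reg_genes) + length(checkpoint_genes) + length(sig_genes) +
    length(set_genes)
  if (n_named > cfg$n_genes)
    .stopf("n_genes = %d too small for %d named genes", cfg$n_genes, n_named)
  filler <- sprintf("GENE%05d", seq_len(cfg$n_genes - n_named))
  genes <- c(reg_genes, checkpoint_genes, sig_genes, set_genes, filler)

  # --- expression --------------------------------------------------------
  set.seed(m6a_seed(cfg$seed, 3L))
  mu <- stats::runif(length(genes), 2, 8)
  names(mu) <- genes
  x <- matrix(stats::rnorm(length(genes) * n, 0, cfg$sigma),
              nrow = length(genes), ncol = n, dimnames = list(genes, sample_ids))
  x <- x + mu
  cen_s <- centers[cluster]
  # regulators + checkpoints: crisp cluster-level shift (the heatmap pattern)
  for (g in c(reg_genes, checkpoint_genes))
    x[g, ] <- x[g, ] + cfg$cluster_shift * cen_s
  # signal genes: follow the per-sample latent score, half up half down
  w <- rep(c(1, -1), length.out = length(sig_genes))
  x[sig_genes, ] <- x[sig_genes, , drop = FALSE] +
    cfg$signal_shift * outer(w, score)
  # signature sets: planted direction times cluster center
  for (col in fixtures) for (s in names(col)) {
    d <- attr(col[[s]], "direction")
    if (d != 0) x[col[[s]], ] <- x[col[[s]], , drop = FALSE] +
        matrix(cfg$set_shift * d * cen_s, length(col[[s]]), n, byrow = TRUE)
  }
  x[x < 0] <- 0 # log2(TPM+1) floor
  expr <- expr_matrix(x, "LOG2_TPM")

  # --- survival ----------------------------------------------------------
  set.seed(m6a_seed(cfg$seed, 4L))
  rates <- cfg$baseline_hazard * exp(cfg$hazard_beta * score)
  t_event <- stats::rexp(n, rates)
  c_rate <- .calibrate_censoring(rates, cfg$censor_rate)
  t_cens <- stats::rexp(n, c_rate)
  os_time <- pmax(pmin(t_event, t_cens), 1 / 24) # at least one hour, in days
  os_event <- as.integer(t_event <= t_cens)
  set.seed(m6a_seed(cfg$seed, 5L))
  clinical <- data.frame(
    sample_id = sample_ids,
    os_time = os_time,
    os_event = os_event,
    age = round(stats::rnorm(n, 65, 9)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    grade = sample(1:4, n, replace = TRUE, prob = c(0.15, 0.4, 0.35, 0.1)),
    stage = sample(1:4, n, replace = TRUE, prob = c(0.2, 0.5, 0.2, 0.1)),
    stringsAsFactors = FALSE
  )

  # --- mutations (MAF-like) ---------------------------------------------
  set.seed(m6a_seed(cfg$seed, 6L))
  lam <- exp(log(cfg$tmb_mean) + cfg$tmb_rho * score)
  n_mut <- stats::rpois(n, lam)
  classes <- c(maf_nonsilent_classes(), "Silent", "3'UTR", "Intron")
  class_p <- c(0.55, 0.04, 0.04, 0.04, 0.02, 0.02, 0.04, 0.01, 0.01, 0.15, 0.04, 0.04)
  recs <- data.frame(
    Tumor_Sample_Barcode = rep(sample_ids, n_mut),
    Hugo_Symbol = sample(genes, sum(n_mut), replace = TRUE),
    Variant_Classification = sample(classes, sum(n_mut), replace = TRUE, prob = class_p),
    Variant_Type = "SNP",
    stringsAsFactors = FALSE
  )

  # --- regulator CNV calls ----------------------------------------------
  set.seed(m6a_seed(cfg$seed, 7L))
  gain_prone <- c("VIRMA", "G3BP1", "YTHDF1", "YTHDF2", "IGF2BP2", "LRPPRC", "FXR1")
  cnv <- matrix("neutral", length(reg_genes), n, dimnames = list(reg_genes, sample_ids))
  for (g in reg_genes) {
    if (g %in% gain_prone) {
      pg <- stats::runif(1, 0.10, 0.30); pl <- stats::runif(1, 0.01, 0.08)
    } else {
      pg <- stats::runif(1, 0.01, 0.08); pl <- stats::runif(1, 0.10, 0.30)
    }
    cnv[g, ] <- sample(c("gain", "loss", "neutral"), n, replace = TRUE,
                       prob = c(pg, pl, 1 - pg - pl))
  }

  structure(list(
    expr = expr, clinical = clinical, mutations = recs,
    cnv = cnv_calls(cnv), gene_sets = fixtures,
    truth = data.frame(sample_id = sample_ids, cluster = unname(cluster),
                       score = unname(score), stringsAsFactors = FALSE),
    config = cfg
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d samples, %d genes, %d planted clusters (seed %d)\n",
              ncol(x$expr), nrow(x$expr), x$config$n_clusters, x$config$seed))
  invisible(x)
}

#' Ground-truth table of a simulated cohort
#'
#' @param cohort a `synthetic_cohort`.
#' @return data.frame with `sample_id`, planted `cluster` label and latent
#'   `score`, one row per sample.
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cohort$truth
}
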