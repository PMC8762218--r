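# The pipeline's core statistic: a PCA-based per-sample score over the
# prognosis-related gene panel (GGI-style), its optimal-cutpoint
# dichotomization, and the downstream integrations: independent prognostic
# analysis, external-cohort validation, tumor mutation burden, the
# regulator correlation/prognosis network, and the three-way attribute
# flow table.

#' Compute the m6Ascore
#'
#' Panel-gene expression is centered (and by default z-scored) across
#' samples, decomposed by SVD, and each sample scored by the sum of its
#' projections on the first two principal components:
#' `m6Ascore_s = PC1_s + PC2_s`. Component signs are made deterministic by
#' forcing the largest-|loading| gene of each component to a positive
#' loading, so reruns are bit-identical; whether high score means good or
#' poor prognosis is a data-driven orientation recorded downstream, not
#' hard-coded.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param panel character vector of panel genes, or a [cox_screen()] result
#'   (its `gene` column is used). At least 3 genes must be present with
#'   non-zero variance.
#' @param scale. z-score genes before the SVD (correlation PCA) so
#'   high-variance genes do not dominate.
#' @return a `score_result`: `scores` data.frame (`sample`, `pc1`, `pc2`,
#'   `m6ascore`), `loadings` (genes x 2, unit norm), `center`, `scale`,
#'   `var_explained`, `anchor_genes` (the sign-orientation record),
#'   `genes_used`.
#' @export
compute_m6ascore <- function(expr, panel, scale. = TRUE) {
  m <- .as_expr_values(expr)
  if (is.data.frame(panel)) panel <- panel$gene
  genes <- intersect(panel, rownames(m))
  if (length(genes) < 3) .stopf("need >= 3 panel genes present; have %d", length(genes))
  X <- t(m[genes, , drop = FALSE]) # samples x genes
  if (nrow(X) < 3) .stopf("need >= 3 samples")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) .stopf("zero-variance panel")
  if (any(sds == 0)) {
    genes <- genes[sds > 0]
    if (length(genes) < 3) .stopf("fewer than 3 panel genes with variance")
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  ctr <- colMeans(X)
  scl <- if (scale.) sds else rep(1, length(genes))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  sv <- svd(Xs, nu = 0, nv = 2)
  V <- sv$v[, 1:2, drop = FALSE]
  if (ncol(V) < 2) V <- cbind(V, 0) # rank-1 input: PC2 identically 0
  rownames(V) <- genes
  anchors <- character(2)
  for (j in 1:2) {
    a <- which.max(abs(V[, j]))
    anchors[j] <- genes[a]
    if (V[a, j] < 0) V[, j] <- -V[, j]
  }
  proj <- Xs %*% V
  d2 <- sv$d^2
  scores <- data.frame(sample = rownames(X), pc1 = proj[, 1], pc2 = proj[, 2],
                       m6ascore = proj[, 1] + proj[, 2],
                       row.names = NULL, stringsAsFactors = FALSE)
  structure(list(scores = scores, loadings = V, center = ctr, scale = scl,
                 var_explained = d2[1:min(2, length(d2))] / sum(d2),
                 anchor_genes = anchors, genes_used = genes,
                 scaled = scale.),
            class = "score_result")
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %d samples, %d panel genes, PC1+PC2 explain %.1f%% variance\n",
              nrow(x$scores), length(x$genes_used), 100 * sum(x$var_explained)))
  invisible(x)
}

#' Dichotomize the m6Ascore and test the survival contrast
#'
#' Splits at the maximally-selected log-rank cutpoint, labels samples
#' high/low, and reports KM curves plus the log-rank test. The naive
#' log-rank p ignores the cutoff selection; request `n_perm > 0` for the
#' selection-corrected permutation p.
#'
#' @param score a `score_result` (or data.frame with `sample`, `m6ascore`).
#' @param clinical clinical table with `sample_id`, `os_time`, `os_event`.
#' @param minprop minimum group proportion for the cutpoint search.
#' @param n_perm permutations for the corrected p (0 = skip).
#' @param seed permutation seed.
#' @return list: `groups` (data.frame sample, m6ascore, group), `cutpoint`,
#'   `survival` ([survival_by_groups()] output), `p_naive`, `p_perm`.
#' @export
dichotomize_score <- function(score, clinical, minprop = 0.1, n_perm = 0,
                              seed = 1) {
  sc <- if (inherits(score, "score_result")) score$scores else score
  stopifnot(all(c("sample", "m6ascore") %in% names(sc)))
  clinical <- validate_clinical(clinical)
  common <- intersect(sc$sample, clinical$sample_id)
  if (length(common) < 10) .stopf("too few samples with both score and survival")
  s <- sc$m6ascore[match(common, sc$sample)]
  cl <- clinical[match(common, clinical$sample_id), ]
  cp <- optimal_cutpoint(s, cl$os_time, cl$os_event, minprop = minprop,
                         n_perm = n_perm, seed = seed)
  grp <- ifelse(s > cp$cutoff, "high", "low")
  sv <- survival_by_groups(cl$os_time, cl$os_event, grp)
  list(groups = data.frame(sample = common, m6ascore = s, group = grp,
                           stringsAsFactors = FALSE),
       cutpoint = cp, survival = sv,
       p_naive = sv$global$p_value, p_perm = cp$p_perm)
}

#' Univariate and multivariate independent prognostic analysis
#'
#' Univariate Cox on the continuous m6Ascore alone, then a multivariate
#' model with age, gender, grade and stage (complete cases; gender coded
#' 0/1). HRs are per unit of score, with no internal rescaling.
#'
#' @param score a `score_result` or data.frame with `sample`, `m6ascore`.
#' @param clinical clinical table with survival plus the covariates.
#' @return list: `univariate`, `multivariate` ([cox_table()] data.frames),
#'   `fits` (the underlying `cox_fit` objects), `n_complete`.
#' @export
independent_prognostic_analysis <- function(score, clinical) {
  sc <- if (inherits(score, "score_result")) score$scores else score
  clinical <- validate_clinical(clinical)
  common <- intersect(sc$sample, clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  s <- sc$m6ascore[match(common, sc$sample)]
  uni <- cox_fit(cl$os_time, cl$os_event,
                 matrix(s, dimnames = list(NULL, "m6ascore")))
  need <- c("age", "gender", "grade", "stage")
  miss <- setdiff(need, names(cl))
  if (length(miss)) .stopf("clinical table missing covariate(s): %s",
                           paste(miss, collapse = ", "))
  gender_num <- if (is.numeric(cl$gender)) cl$gender
                else as.numeric(factor(cl$gender)) - 1
  X <- cbind(m6ascore = s, age = as.numeric(cl$age), gender = gender_num,
             grade = as.numeric(cl$grade), stage = as.numeric(cl$stage))
  cc <- stats::complete.cases(X)
  multi <- cox_fit(cl$os_time[cc], cl$os_event[cc], X[cc, , drop = FALSE])
  list(univariate = cox_table(uni), multivariate = cox_table(multi),
       fits = list(univariate = uni, multivariate = multi),
       n_complete = sum(cc))
}

#' Project an external cohort through a trained score model
#'
#' Freezes the training loadings, centering and scaling and projects the
#' external samples onto them; the high/low cutoff is re-estimated on the
#' external cohort (each cohort is dichotomized at its own optimal cutoff).
#' Runs with partial panel coverage (>= 3 genes), reporting the coverage
#' fraction; projecting the training matrix itself reproduces the training
#' scores.
#'
#' @param score_model a `score_result` from [compute_m6ascore()].
#' @param expr_external genes x samples matrix of the external cohort.
#' @param clinical_external optional clinical table; when supplied the
#'   high/low survival contrast is computed.
#' @param minprop cutpoint constraint.
#' @return list: `scores` (sample, pc1, pc2, m6ascore), `coverage`
#'   (fraction of panel genes present), `missing_genes`, and when clinical
#'   is given `contrast` (a [dichotomize_score()] result).
#' @export
validate_external <- function(score_model, expr_external,
                              clinical_external = NULL, minprop = 0.1) {
  stopifnot(inherits(score_model, "score_result"))
  m <- .as_expr_values(expr_external)
  genes <- score_model$genes_used
  present <- intersect(genes, rownames(m))
  missing <- setdiff(genes, present)
  if (length(present) < 3)
    .stopf("external cohort shares only %d/%d panel genes (need >= 3); missing: %s",
           length(present), length(genes), paste(utils::head(missing, 10), collapse = ", "))
  if (length(missing))
    message(sprintf("validate_external: %d/%d panel genes present (coverage %.2f)",
                    length(present), length(genes), length(present) / length(genes)))
  X <- t(m[present, , drop = FALSE])
  ix <- match(present, genes)
  Xs <- sweep(sweep(X, 2, score_model$center[ix]), 2, score_model$scale[ix], "/")
  proj <- Xs %*% score_model$loadings[ix, , drop = FALSE]
  scores <- data.frame(sample = rownames(X), pc1 = proj[, 1], pc2 = proj[, 2],
                       m6ascore = proj[, 1] + proj[, 2],
                       row.names = NULL, stringsAsFactors = FALSE)
  out <- list(scores = scores, coverage = length(present) / length(genes),
              missing_genes = missing)
  if (!is.null(clinical_external))
    out$contrast <- dichotomize_score(scores, clinical_external, minprop = minprop)
  out
}

#' Tumor mutation burden integration
#'
#' Per-sample non-silent mutation counts from a MAF-style table, their
#' Spearman correlation with the m6Ascore, TMB dichotomization at the
#' optimal survival cutpoint, and the joint four-group
#' (TMB high/low x score high/low) survival stratification.
#'
#' @param score_groups [dichotomize_score()] output (uses `groups`).
#' @param muts MAF-style mutation table.
#' @param clinical clinical table.
#' @param per_mb also report counts / `exome_mb`.
#' @param exome_mb assayed exome size in megabases (38 by convention).
#' @param minprop cutpoint constraint for the TMB split.
#' @return list: `tmb` (sample, tmb_count, optional tmb_per_mb, tmb_group,
#'   score_group), `correlation` (rho, p_value, n), `cutpoint`,
#'   `joint_survival` (four-curve [survival_by_groups()]), `excluded`
#'   (samples without mutation data are absent from the table by
#'   construction of a MAF; samples lacking survival are dropped).
#' @export
tmb_integration <- function(score_groups, muts, clinical, per_mb = FALSE,
                            exome_mb = 38, minprop = 0.1) {
  stopifnot(is.list(score_groups), !is.null(score_groups$groups))
  clinical <- validate_clinical(clinical)
  grp <- score_groups$groups
  ns <- muts[muts$Variant_Classification %in% maf_nonsilent_classes(), ]
  counts <- table(factor(ns$Tumor_Sample_Barcode, levels = grp$sample))
  tmb <- data.frame(sample = grp$sample,
                    tmb_count = as.integer(counts[grp$sample]),
                    stringsAsFactors = FALSE)
  if (per_mb) tmb$tmb_per_mb <- tmb$tmb_count / exome_mb
  common <- intersect(tmb$sample, clinical$sample_id)
  excluded <- setdiff(grp$sample, common)
  tmb <- tmb[tmb$sample %in% common, ]
  cl <- clinical[match(tmb$sample, clinical$sample_id), ]
  sc <- grp$m6ascore[match(tmb$sample, grp$sample)]
  corr <- spearman_cor(sc, tmb$tmb_count)
  cp <- optimal_cutpoint(tmb$tmb_count, cl$os_time, cl$os_event,
                         minprop = minprop)
  tmb$tmb_group <- ifelse(tmb$tmb_count > cp$cutoff, "highTMB", "lowTMB")
  tmb$score_group <- grp$group[match(tmb$sample, grp$sample)]
  joint <- survival_by_groups(cl$os_time, cl$os_event,
                              paste(tmb$tmb_group, tmb$score_group, sep = "."))
  list(tmb = tmb, correlation = corr, cutpoint = cp, joint_survival = joint,
       excluded = excluded)
}

#' Regulator correlation and prognosis network
#'
#' Pairwise Spearman correlations among the registry regulators present in
#' the expression matrix (edges kept at BH-adjusted p below the threshold)
#' and a per-regulator univariate Cox classification: risk (HR > 1,
#' p < 0.05), protective (HR < 1, p < 0.05), otherwise ns. Absent
#' regulators are flagged and excluded from edges.
#'
#' @param expr genes x samples matrix.
#' @param clinical clinical table.
#' @param registry regulator registry (default [load_regulator_registry()]).
#' @param adj_p_threshold edge significance threshold on adjusted p.
#' @param prog_p_threshold per-gene Cox significance threshold.
#' @return list: `nodes` (symbol, role, present, prognosis, HR, p),
#'   `edges` (gene_a, gene_b, rho, p, p_adj, sign).
#' @export
regulator_network <- function(expr, clinical,
                              registry = load_regulator_registry(),
                              adj_p_threshold = 0.05,
                              prog_p_threshold = 0.05) {
  m <- .as_expr_values(expr)
  clinical <- validate_clinical(clinical)
  common <- intersect(colnames(m), clinical$sample_id)
  cl <- clinical[match(common, clinical$sample_id), ]
  present <- registry$symbol %in% rownames(m)
  nodes <- data.frame(symbol = registry$symbol, role = registry$role,
                      present = present, prognosis = "absent",
                      HR = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  for (i in which(present)) {
    g <- registry$symbol[i]
    xg <- m[g, common]
    if (stats::sd(xg) == 0) next
    fit <- tryCatch(cox_fit(cl$os_time, cl$os_event,
                            matrix(xg, dimnames = list(NULL, g))),
                    error = function(e) NULL)
    if (is.null(fit)) next
    nodes$HR[i] <- fit$HR[1]; nodes$p[i] <- fit$p[1]
    nodes$prognosis[i] <- if (fit$p[1] >= prog_p_threshold) "ns"
                          else if (fit$HR[1] > 1) "risk" else "protective"
  }
  syms <- registry$symbol[present]
  edges <- NULL
  if (length(syms) >= 2) {
    pairs <- utils::combn(syms, 2)
    res <- apply(pairs, 2, function(pr) {
      sp <- spearman_cor(m[pr[1], common], m[pr[2], common])
      c(rho = sp$rho, p = sp$p_value)
    })
    edges <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                        rho = res["rho", ], p = res["p", ],
                        stringsAsFactors = FALSE)
    edges$p_adj <- bh_adjust(edges$p)
    edges <- edges[edges$p_adj < adj_p_threshold, , drop = FALSE]
    edges$sign <- ifelse(edges$rho > 0, "positive", "negative")
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

#' Three-way attribute flow table
#'
#' One row per sample carrying its m6Acluster, gene-cluster and score-group
#' labels (the alluvial-diagram data), plus the three-way cross-tabulation.
#' All three labelings must cover exactly the same samples.
#'
#' @param m6aclusters,gene_clusters,score_groups named label vectors over
#'   identical sample sets.
#' @return data.frame `sample`, `m6acluster`, `gene_cluster`,
#'   `score_group`; attribute `crosstab`.
#' @export
attribute_flow_table <- function(m6aclusters, gene_clusters, score_groups) {
  ids <- names(m6aclusters)
  if (is.null(ids) || is.null(names(gene_clusters)) || is.null(names(score_groups)))
    .stopf("all three labelings must be named by sample")
  if (!setequal(ids, names(gene_clusters)) || !setequal(ids, names(score_groups)))
    .stopf("labelings cover different sample sets")
  out <- data.frame(sample = ids,
                    m6acluster = unname(m6aclusters[ids]),
                    gene_cluster = unname(gene_clusters[ids]),
                    score_group = unname(score_groups[ids]),
                    stringsAsFactors = FALSE)
  attr(out, "crosstab") <- table(m6acluster = out$m6acluster,
                                 gene_cluster = out$gene_cluster,
                                 score_group = out$score_group)
  out
}
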