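# End-to-end orchestration: simulate (or ingest) -> consensus cluster on
# regulators -> enrichment scoring -> moderated DEG + Cox screen ->
# gene-cluster consensus -> m6Ascore -> survival / TMB / network
# integrations, with a machine-readable run report. Stage order mirrors the
# analysis narrative; every intermediate is written as TSV/JSON so a run
# directory is self-describing.

#' Pipeline configuration
#'
#' A single flat list, serializable to JSON and round-trippable unchanged.
#' `preset = "planted"` simulates the default ground-truth world;
#' `preset = "null"` zeroes the cluster shift, signal shift, hazard and
#' TMB slope (every downstream signal should then be noise).
#'
#' @param preset `"planted"` or `"null"`.
#' @param n_samples cohort size for simulation.
#' @param seed master seed.
#' @param deg_p raw-p DEG criterion.
#' @param cox_p univariate Cox screen criterion.
#' @param adj_p adjusted-p threshold for enrichment contrasts and network
#'   edges.
#' @param minprop cutpoint group-proportion constraint.
#' @param k_range consensus k candidates.
#' @param n_resamples consensus resamples.
#' @param alpha ssGSEA rank-weight exponent.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(preset = c("planted", "null"), n_samples = 150,
                            seed = 1, deg_p = 1e-4, cox_p = 1e-3,
                            adj_p = 0.05, minprop = 0.1, k_range = 2:6,
                            alpha = 0.25, n_resamples = 500,
                            outdir = tempfile("m6a_run_")) {
  preset <- match.arg(preset)
  for (nm in c("deg_p", "cox_p", "adj_p", "minprop")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) .stopf("%s must be inside (0, 1)", nm)
  }
  structure(list(preset = preset, n_samples = n_samples, seed = as.integer(seed),
                 deg_p = deg_p, cox_p = cox_p, adj_p = adj_p,
                 minprop = minprop, k_range = as.integer(k_range),
                 alpha = alpha, n_resamples = as.integer(n_resamples),
                 outdir = outdir),
            class = "pipeline_config")
}

.cfg_to_sim <- function(cfg) {
  if (cfg$preset == "null")
    sim_config(n_samples = cfg$n_samples, seed = cfg$seed, cluster_shift = 0,
               signal_shift = 0, set_shift = 0, hazard_beta = 0, tmb_rho = 0)
  else
    sim_config(n_samples = cfg$n_samples, seed = cfg$seed)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> regulator consensus clustering -> enrichment ->
#' DEG/Cox screens -> gene-cluster consensus -> m6Ascore -> survival, TMB
#' and network integrations, writing every intermediate under
#' `cfg$outdir`. Identical seeds give byte-identical artifacts. When the
#' prognostic panel has fewer than 3 genes (expected under the null
#' preset) the score-dependent stages are skipped and recorded as such.
#'
#' @param cfg a [pipeline_config()].
#' @return a `run_report` list (also written as `report.json`): versions,
#'   config and its hash, per-stage record counts, selected k per
#'   clustering, and captured warnings.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, conditionMessage(w))
  stage <- function(name, code) {
    withCallingHandlers(
      tryCatch(code, error = function(e)
        .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))),
      warning = function(w) { note(w); invokeRestart("muffleWarning") })
  }
  # outdir is a runtime location, not an analysis parameter: keep it out of
  # the serialized config so identical seeds give byte-identical artifacts
  cfg_ser <- unclass(cfg)
  cfg_ser$outdir <- NULL
  report <- list(package = "m6Apatterns",
                 version = as.character(utils::packageVersion("m6Apatterns")),
                 config = cfg_ser)
  report$config_hash <- .fnv1a(jsonlite::toJSON(cfg_ser, auto_unbox = TRUE,
                                                digits = NA))

  cohort <- stage("simulate", simulate_cohort(.cfg_to_sim(cfg)))
  write_expression(cohort$expr, file.path(cfg$outdir, "expression.tsv"))
  .write_tsv(cohort$clinical, file.path(cfg$outdir, "clinical.tsv"))
  .write_tsv(cohort$mutations, file.path(cfg$outdir, "mutations.maf"))
  .write_tsv(as.data.frame(unclass(cohort$cnv)), file.path(cfg$outdir, "cnv_calls.tsv"),
             rownames_col = "gene")
  .write_tsv(cohort$truth, file.path(cfg$outdir, "truth.tsv"))
  for (nm in names(cohort$gene_sets))
    write_gmt(cohort$gene_sets[[nm]], file.path(cfg$outdir, paste0("sets_", nm, ".gmt")))
  report$n_samples <- ncol(cohort$expr)
  report$n_genes <- nrow(cohort$expr)

  registry <- load_regulator_registry()
  reg_expr <- cohort$expr[intersect(registry$symbol, rownames(cohort$expr)), ,
                          drop = FALSE]
  m6acl <- stage("m6acluster", consensus_cluster(
    reg_expr, k_range = cfg$k_range, n_resamples = cfg$n_resamples,
    seed = m6a_seed(cfg$seed, 11L)))
  .write_tsv(data.frame(sample = names(m6acl$partition),
                        m6acluster = unname(m6acl$partition)),
             file.path(cfg$outdir, "m6aclusters.tsv"))
  jsonlite::write_json(list(selected_k = m6acl$selected_k,
                            delta_area = as.list(m6acl$delta_area)),
                       file.path(cfg$outdir, "m6acluster_selection.json"),
                       auto_unbox = TRUE, digits = NA)
  report$m6acluster_k <- m6acl$selected_k
  report$m6acluster_sizes <- as.list(table(m6acl$partition))
  stage("cluster_survival", {
    sv <- survival_by_groups(cohort$clinical$os_time, cohort$clinical$os_event,
                             m6acl$partition[cohort$clinical$sample_id])
    .write_tsv(data.frame(contrast = "global", statistic = sv$global$statistic,
                          p = sv$global$p_value), file.path(cfg$outdir, "m6acluster_logrank.tsv"))
  })

  enr <- stage("enrichment", {
    imm <- ssgsea_score(cohort$expr, cohort$gene_sets$immune, alpha = cfg$alpha)
    est <- estimate_scores(cohort$expr, cohort$gene_sets$estimate$ESTIMATE_stromal,
                           cohort$gene_sets$estimate$ESTIMATE_immune,
                           alpha = cfg$alpha)
    pw <- pathway_activity(cohort$expr, cohort$gene_sets$pathway, alpha = cfg$alpha)
    landscape <- immune_landscape_table(imm, m6acl$partition)
    .write_tsv(as.data.frame(imm), file.path(cfg$outdir, "immune_scores.tsv"),
               rownames_col = "sample")
    .write_tsv(est, file.path(cfg$outdir, "estimate_scores.tsv"))
    .write_tsv(as.data.frame(pw), file.path(cfg$outdir, "pathway_scores.tsv"),
               rownames_col = "sample")
    .write_tsv(landscape, file.path(cfg$outdir, "immune_landscape.tsv"))
    list(immune = imm, estimate = est, pathway = pw)
  })
  report$n_signatures <- ncol(enr$immune)

  if (min(table(m6acl$partition)) >= 2) {
    deg <- stage("deg", moderated_anova(cohort$expr, m6acl$partition))
    degs <- select_degs(deg, cfg$deg_p)
    .write_tsv(deg, file.path(cfg$outdir, "deg_table.tsv"))
  } else {
    # a singleton consensus cluster (expected under the null preset) cannot
    # support a between-cluster variance estimate: record an empty screen
    warnings_log <- c(warnings_log,
                      "deg stage skipped: a consensus cluster has < 2 samples")
    degs <- character(0)
    .write_tsv(data.frame(gene = character(0), F = numeric(0), p = numeric(0),
                          p_adj = numeric(0)),
               file.path(cfg$outdir, "deg_table.tsv"))
  }
  writeLines(degs, file.path(cfg$outdir, "deg_genes.txt"))
  report$n_degs <- length(degs)

  panel <- NULL
  if (length(degs) >= 1) {
    panel <- stage("cox_screen", cox_screen(cohort$expr, cohort$clinical,
                                            degs, cfg$cox_p))
    .write_tsv(panel, file.path(cfg$outdir, "prognostic_panel.tsv"))
  }
  report$panel_size <- if (is.null(panel)) 0L else nrow(panel)

  if (report$panel_size >= 3) {
    gcl <- stage("gene_cluster", consensus_cluster(
      cohort$expr[panel$gene, , drop = FALSE], k_range = cfg$k_range,
      n_resamples = cfg$n_resamples, seed = m6a_seed(cfg$seed, 12L)))
    .write_tsv(data.frame(sample = names(gcl$partition),
                          gene_cluster = unname(gcl$partition)),
               file.path(cfg$outdir, "gene_clusters.tsv"))
    report$gene_cluster_k <- gcl$selected_k

    sc <- stage("score", compute_m6ascore(cohort$expr, panel))
    dich <- stage("dichotomize", dichotomize_score(sc, cohort$clinical,
                                                   minprop = cfg$minprop))
    .write_tsv(dich$groups, file.path(cfg$outdir, "m6ascore.tsv"))
    .write_tsv(data.frame(gene = rownames(sc$loadings), sc$loadings),
               file.path(cfg$outdir, "score_loadings.tsv"))
    report$score_cutoff <- dich$cutpoint$cutoff
    report$score_logrank_p <- dich$p_naive

    prog <- stage("prognostic", independent_prognostic_analysis(sc, cohort$clinical))
    .write_tsv(prog$univariate, file.path(cfg$outdir, "cox_univariate.tsv"))
    .write_tsv(prog$multivariate, file.path(cfg$outdir, "cox_multivariate.tsv"))
    report$score_hr_univariate <- prog$univariate$HR[1]
    report$score_hr_multivariate <-
      prog$multivariate$HR[prog$multivariate$term == "m6ascore"]

    auc <- stage("td_auc", {
      ix <- match(dich$groups$sample, cohort$clinical$sample_id)
      td_auc(dich$groups$m6ascore, cohort$clinical$os_time[ix],
             cohort$clinical$os_event[ix])
    })
    .write_tsv(auc, file.path(cfg$outdir, "td_auc.tsv"))
    report$auc <- stats::setNames(as.list(auc$auc_oriented),
                                  paste0("year_", auc$horizon_years))

    tmb <- stage("tmb", tmb_integration(dich, cohort$mutations, cohort$clinical,
                                        minprop = cfg$minprop))
    .write_tsv(tmb$tmb, file.path(cfg$outdir, "tmb.tsv"))
    report$tmb_spearman_rho <- tmb$correlation$rho

    net <- stage("network", regulator_network(cohort$expr, cohort$clinical,
                                              adj_p_threshold = cfg$adj_p))
    .write_tsv(net$nodes, file.path(cfg$outdir, "network_nodes.tsv"))
    if (!is.null(net$edges))
      .write_tsv(net$edges, file.path(cfg$outdir, "network_edges.tsv"))
    report$network_edges <- if (is.null(net$edges)) 0L else nrow(net$edges)

    flow <- stage("flow", attribute_flow_table(
      m6acl$partition, gcl$partition,
      stats::setNames(dich$groups$group, dich$groups$sample)))
    .write_tsv(flow, file.path(cfg$outdir, "attribute_flow.tsv"))
  } else {
    report$skipped_stages <- c("gene_cluster", "score", "dichotomize",
                               "prognostic", "td_auc", "tmb", "network", "flow")
  }

  report$warnings <- warnings_log
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(jsonlite::toJSON(cfg_ser, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             file.path(cfg$outdir, "config.json"))
  class(report) <- "run_report"
  invisible(report)
}

#' One-page digest of a completed run
#'
#' Reads the stored artifacts only (no recomputation) and summarizes the
#' selected k values, cluster sizes, panel size, score hazard ratios and
#' the AUC table. An incomplete run directory fails naming the first
#' missing artifact.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of digest lines (also printed).
#' @export
summarize_run <- function(run_dir) {
  need <- c("report.json", "m6aclusters.tsv", "deg_table.tsv")
  for (f in need)
    if (!file.exists(file.path(run_dir, f)))
      .stopf("incomplete run: missing artifact '%s'", f)
  rep <- jsonlite::read_json(file.path(run_dir, "report.json"))
  lines <- c(
    sprintf("m6Apatterns run digest (%s)", run_dir),
    sprintf("  cohort: %d samples x %d genes (preset %s, seed %d)",
            rep$n_samples, rep$n_genes, rep$config$preset, rep$config$seed),
    sprintf("  m6Acluster consensus: selected_k = %s, sizes %s",
            rep$m6acluster_k,
            paste(names(rep$m6acluster_sizes), unlist(rep$m6acluster_sizes),
                  sep = "=", collapse = ", ")),
    sprintf("  DEG screen: %d genes at p < %g; prognostic panel: %d genes at p < %g",
            rep$n_degs, rep$config$deg_p, rep$panel_size, rep$config$cox_p))
  if (!is.null(rep$gene_cluster_k))
    lines <- c(lines, sprintf("  gene-cluster consensus: selected_k = %s",
                              rep$gene_cluster_k))
  if (!is.null(rep$score_hr_univariate))
    lines <- c(lines,
               sprintf("  m6Ascore: HR %.3f (univariate), %.3f (multivariate); log-rank p = %.3g",
                       rep$score_hr_univariate, rep$score_hr_multivariate,
                       rep$score_logrank_p),
               sprintf("  AUC: %s", paste(names(rep$auc),
                                          sprintf("%.3f", unlist(rep$auc)),
                                          sep = "=", collapse = ", ")),
               sprintf("  TMB-score Spearman rho = %.3f", rep$tmb_spearman_rho))
  if (!is.null(rep$skipped_stages))
    lines <- c(lines, sprintf("  skipped stages: %s",
                              paste(unlist(rep$skipped_stages), collapse = ", ")))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
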