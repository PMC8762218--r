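# Independent oracles and shared fixtures for the suite. Oracles are
# deliberately written from the definitions, not by calling package code.

# Brute-force ssGSEA running sum for one sample vector x (named) and one
# gene set: steps down the expression-ordered list accumulating the
# weighted in-set fraction minus the out-of-set fraction.
oracle_ssgsea <- function(x, set_genes, alpha) {
  stopifnot(!is.null(names(x)))
  N <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(x, decreasing = TRUE)
  inset <- names(x) %in% set_genes
  m <- sum(inset)
  denom <- sum(r[inset]^alpha)
  p_in <- 0; p_out <- 0; es <- 0
  for (i in ord) {
    if (inset[i]) p_in <- p_in + r[i]^alpha / denom
    else p_out <- p_out + 1 / (N - m)
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Plain concordance fraction of case/control marker pairs at horizon t0
# (the censoring-free limit of the IPCW AUC).
oracle_concordance <- function(marker, time, t0) {
  cases <- which(time <= t0)
  ctrl <- which(time > t0)
  cmp <- outer(marker[cases], marker[ctrl], ">") +
    0.5 * outer(marker[cases], marker[ctrl], "==")
  mean(cmp)
}

# Map arbitrary consensus labels onto planted truth labels by majority
# vote, so "cluster-B analog" claims can be asserted.
map_to_truth <- function(partition, truth_labels) {
  truth_labels <- truth_labels[names(partition)]
  vapply(split(truth_labels, partition),
         function(v) names(which.max(table(v))), character(1))
}

# Cohort cache: simulation is deterministic, so share cohorts across tests.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(..., key = NULL) {
  cfg <- sim_config(...)
  key <- key %||% paste0("c", .fnv_key(cfg))
  if (is.null(.cohort_cache[[key]]))
    .cohort_cache[[key]] <- simulate_cohort(cfg)
  .cohort_cache[[key]]
}
.fnv_key <- function(cfg) paste(unlist(cfg), collapse = "_")
`%||%` <- function(a, b) if (is.null(a)) b else a

# Truth-labelled partition of a cohort.
truth_partition <- function(cohort) {
  stats::setNames(cohort$truth$cluster, cohort$truth$sample_id)
}
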