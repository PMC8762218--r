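# Single-sample gene-set scoring: the ssGSEA running-sum score for
# immune-cell and pathway signatures, and ESTIMATE-style stromal/immune/
# combined scores built on the same engine.

# ssGSEA score of one set in one sample.
# r: average ranks of the sample's expression (1 = lowest, N = highest);
# ord: gene order by decreasing expression (ties resolved by index).
.ssgsea_one <- function(r, ord, in_set, alpha) {
  N <- length(r)
  m <- sum(in_set)
  inn <- in_set[ord]
  w <- (r[ord]^alpha) * inn
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!inn) / (N - m)
  sum(p_in - p_out)
}

#' ssGSEA single-sample enrichment scores
#'
#' Per sample, genes are ranked by expression (average ranks for ties) and
#' each retained set scored by the integrated running-sum statistic: the
#' cumulative weighted in-set fraction (weights `rank^alpha`, normalized)
#' minus the cumulative out-of-set fraction, summed over the ranked list.
#' Being rank-based, scores are invariant to any strictly increasing
#' transform of a sample's expression values. Optional cohort normalization
#' divides the whole score matrix by its (max - min).
#'
#' @param expr genes x samples numeric matrix (log2 scale conventional).
#' @param sets named list of gene-symbol sets (e.g. from [read_gmt()]).
#' @param alpha rank-weighting exponent (0.25 is the ssGSEA convention).
#' @param min_overlap sets with fewer genes present in `expr` are dropped
#'   with a warning.
#' @param normalize divide all scores by the matrix-wide (max - min).
#' @return samples x signatures numeric matrix; attributes `method`,
#'   `alpha`, `normalized`, `dropped` (set names that failed the overlap
#'   filter).
#' @export
ssgsea_score <- function(expr, sets, alpha = 0.25, min_overlap = 5,
                         normalize = TRUE) {
  m <- .as_expr_values(expr)
  if (alpha < 0) .stopf("alpha must be >= 0")
  if (!length(sets) || is.null(names(sets))) .stopf("sets must be a named list")
  universe <- rownames(m)
  overlap <- lapply(sets, function(s) intersect(unique(s), universe))
  keep <- lengths(overlap) >= min_overlap & lengths(overlap) < length(universe)
  dropped <- names(sets)[!keep]
  if (length(dropped))
    .warnf("dropped %d set(s) below min_overlap = %d: %s", length(dropped),
           min_overlap, paste(dropped, collapse = ", "))
  overlap <- overlap[keep]
  if (!length(overlap)) .stopf("no gene set passes the overlap filter")
  sd0 <- apply(m, 2, function(x) max(x) - min(x))
  if (any(sd0 == 0)) .stopf("all-tied expression in sample(s): %s",
                            paste(colnames(m)[sd0 == 0], collapse = ", "))
  in_mat <- vapply(overlap, function(s) universe %in% s,
                   logical(length(universe)))
  scores <- matrix(NA_real_, ncol(m), length(overlap),
                   dimnames = list(colnames(m), names(overlap)))
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    for (s in seq_along(overlap))
      scores[j, s] <- .ssgsea_one(r, ord, in_mat[, s], alpha)
  }
  normalized <- FALSE
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) { scores <- scores / rng; normalized <- TRUE }
  }
  structure(scores, method = "ssgsea", alpha = alpha, normalized = normalized,
            dropped = dropped)
}

#' ESTIMATE-style stromal/immune/combined scores
#'
#' Unnormalized ssGSEA scores of a stromal and an immune signature; the
#' combined score is exactly their sum. High combined score indicates low
#' tumor purity.
#'
#' @param expr genes x samples matrix.
#' @param stromal_set,immune_set character vectors of gene symbols.
#' @param alpha rank-weight exponent.
#' @param min_overlap minimum genes present per signature.
#' @return data.frame: `sample`, `stromal_score`, `immune_score`,
#'   `estimate_score`.
#' @export
estimate_scores <- function(expr, stromal_set, immune_set, alpha = 0.25,
                            min_overlap = 5) {
  sc <- ssgsea_score(expr, list(stromal = stromal_set, immune = immune_set),
                     alpha = alpha, min_overlap = min_overlap, normalize = FALSE)
  if (ncol(sc) < 2) .stopf("stromal or immune signature failed the overlap filter")
  data.frame(sample = rownames(sc),
             stromal_score = sc[, "stromal"],
             immune_score = sc[, "immune"],
             estimate_score = sc[, "stromal"] + sc[, "immune"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-sample pathway activity scores
#'
#' The same single-sample engine applied to pathway collections, feeding
#' the between-cluster pathway contrasts. (The kernel-smoothed GSVA variant
#' is deliberately not implemented; this rank running-sum score is the one
#' methodological substitution, see the methods vignette.)
#'
#' @inheritParams ssgsea_score
#' @param pathway_sets named list of pathway gene sets.
#' @return samples x pathways score matrix (unnormalized).
#' @export
pathway_activity <- function(expr, pathway_sets, alpha = 0.25, min_overlap = 5) {
  ssgsea_score(expr, pathway_sets, alpha = alpha, min_overlap = min_overlap,
               normalize = FALSE)
}

#' Immune landscape comparison across clusters
#'
#' Per signature: per-cluster medians, a Kruskal-Wallis p, the BH-adjusted
#' p over all signatures, and significance stars (* < 0.05, ** < 0.01,
#' *** < 0.001 on the adjusted value).
#'
#' @param scores samples x signatures matrix (e.g. from [ssgsea_score()]).
#' @param partition named cluster labels covering the scored samples.
#' @return data.frame, one row per signature: median per cluster, `p`,
#'   `p_adj`, `stars`.
#' @export
immune_landscape_table <- function(scores, partition) {
  stopifnot(is.matrix(scores))
  if (!is.null(names(partition))) partition <- partition[rownames(scores)]
  if (length(partition) != nrow(scores) || any(is.na(partition)))
    .stopf("partition must cover every scored sample")
  cl <- as.character(partition)
  lev <- sort(unique(cl))
  med <- t(apply(scores, 2, function(v) vapply(split(v, cl), stats::median, numeric(1))))
  colnames(med) <- paste0("median_", lev)
  p <- apply(scores, 2, function(v) kruskal_wallis(split(v, cl))$p_value)
  p_adj <- bh_adjust(p)
  data.frame(signature = colnames(scores), med, p = p, p_adj = p_adj,
             stars = significance_stars(p_adj),
             row.names = NULL, stringsAsFactors = FALSE, check.names = FALSE)
}
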