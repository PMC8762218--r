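# Resampling-based consensus clustering with CDF/delta-area selection of
# the number of clusters. Used twice in the pipeline: on regulator
# expression (m6Aclusters) and on the prognosis-related gene panel (gene
# clusters).

# One resampled clustering; returns integer labels for the subsampled items.
.base_cluster <- function(feat, k, method) {
  if (method == "kmeans") {
    for (attempt in 1:5) {
      fit <- tryCatch(stats::kmeans(feat, centers = k, nstart = 1, iter.max = 50),
                      error = function(e) NULL)
      if (!is.null(fit)) return(fit$cluster)
    }
    # duplicated points can defeat random center draws; fall back to hclust
    stats::cutree(stats::hclust(stats::dist(feat), method = "average"), k)
  } else {
    stats::cutree(stats::hclust(stats::dist(feat), method = "average"), k)
  }
}

#' Consensus clustering over a range of k
#'
#' For each k in `k_range`, repeatedly subsamples `subsample_fraction` of
#' the samples without replacement, clusters the subsample
#' (average-linkage hierarchical clustering on Euclidean distance of
#' per-gene z-scored features by default; k-means available), and records
#' how often each pair
#' of samples co-clusters among the resamples where both were drawn:
#' `M(i, j) = co-clustered / co-sampled`. The final partition at each k is
#' an average-linkage hierarchical cut of `1 - M`. The number of clusters
#' is selected from the consensus CDFs by the proportional delta-area
#' elbow rule (see [cdf_delta_area()]).
#'
#' @param features genes x samples numeric matrix (an [expr_matrix()] works).
#' @param k_range integer vector of candidate k, inside \[2, n - 1\].
#' @param n_resamples number of subsampling iterations per k.
#' @param subsample_fraction fraction of samples drawn per iteration.
#' @param base_method `"hclust"` (average linkage, Euclidean; the default
#'   of the reference consensus-clustering implementation, and the one
#'   under which the delta-area elbow is well behaved on crisp structure)
#'   or `"kmeans"`.
#' @param seed master seed; resample r uses the derived seed stream r.
#' @param scale_features z-score each gene before clustering (recommended so
#'   high-expression genes do not dominate Euclidean distance).
#' @param elbow_threshold relative delta-area threshold for k selection.
#' @return a `consensus_result`: list with `consensus` (per-k matrices),
#'   `cdf`, `delta_area`, `selected_k`, `partition` (named cluster labels
#'   A, B, ...), and the parameters used.
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_resamples = 500,
                              subsample_fraction = 0.8,
                              base_method = c("hclust", "kmeans"), seed = 1,
                              scale_features = TRUE, elbow_threshold = 0.1) {
  base_method <- match.arg(base_method)
  m <- .as_expr_values(features)
  if (any(!is.finite(m))) .stopf("features must be finite")
  n <- ncol(m)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    .stopf("k_range must lie inside [2, n - 1]")
  if (subsample_fraction <= 0 || subsample_fraction > 1)
    .stopf("subsample_fraction must be in (0, 1]")
  feat <- t(m) # samples x genes
  if (scale_features) {
    sds <- apply(feat, 2, stats::sd)
    keep <- sds > 0
    feat <- scale(feat[, keep, drop = FALSE])
  }
  n_sub <- max(2L, floor(subsample_fraction * n))
  ids <- colnames(m) %||% as.character(seq_len(n))

  consensus <- list()
  for (k in k_range) {
    co_cluster <- matrix(0, n, n)
    co_sample <- matrix(0, n, n)
    for (r in seq_len(n_resamples)) {
      set.seed(m6a_seed(seed, k * 1000000L + r))
      sel <- sample.int(n, n_sub)
      cl <- .base_cluster(feat[sel, , drop = FALSE], k, base_method)
      same <- outer(cl, cl, "==") * 1
      co_cluster[sel, sel] <- co_cluster[sel, sel] + same
      co_sample[sel, sel] <- co_sample[sel, sel] + 1
    }
    if (any(co_sample[upper.tri(co_sample)] == 0))
      .stopf("some sample pairs were never co-sampled; increase n_resamples")
    M <- co_cluster / co_sample
    diag(M) <- 1
    dimnames(M) <- list(ids, ids)
    consensus[[as.character(k)]] <- M
  }

  sel <- cdf_delta_area(consensus, elbow_threshold = elbow_threshold)
  k_star <- sel$selected_k
  hc <- stats::hclust(stats::as.dist(1 - consensus[[as.character(k_star)]]),
                      method = "average")
  part_int <- stats::cutree(hc, k_star)
  # stable labels: A = cluster of the first sample, etc.
  lab <- stats::setNames(LETTERS[seq_len(k_star)], unique(part_int))
  partition <- stats::setNames(unname(lab[as.character(part_int)]), ids)

  structure(list(
    consensus = consensus, cdf = sel$cdf, delta_area = sel$delta_area,
    selected_k = k_star, partition = partition,
    n_resamples = n_resamples, subsample_fraction = subsample_fraction,
    base_method = base_method, seed = seed, k_range = k_range
  ), class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("<consensus_result> selected k = %d (k range %d..%d, %d resamples)\n",
              x$selected_k, min(x$k_range), max(x$k_range), x$n_resamples))
  print(table(x$partition))
  invisible(x)
}

#' CDF and delta-area k selection from consensus matrices
#'
#' For each k, the empirical CDF of the upper-triangle consensus values is
#' integrated over \[0, 1\] to an area A(k). Delta-area is `A(k_min)` for
#' the smallest k and the relative increase `(A(k) - A(k-1)) / A(k-1)`
#' thereafter. The selected k is the largest k whose delta-area is at least
#' `elbow_threshold` (falling back to the smallest k when none clears it).
#'
#' @param consensus_matrices named list of symmetric consensus matrices,
#'   names = k (consecutive).
#' @param elbow_threshold relative delta-area threshold.
#' @return list with `cdf` (per-k function), `area`, `delta_area`,
#'   `selected_k`.
#' @export
cdf_delta_area <- function(consensus_matrices, elbow_threshold = 0.1) {
  ks <- as.integer(names(consensus_matrices))
  if (!length(ks)) .stopf("no consensus matrices supplied")
  if (length(ks) == 1) warning("single k supplied; selection is trivial", call. = FALSE)
  cdf <- list(); area <- numeric(length(ks)); names(area) <- names(consensus_matrices)
  for (i in seq_along(ks)) {
    M <- consensus_matrices[[i]]
    v <- sort(M[upper.tri(M)])
    F <- stats::ecdf(v)
    cdf[[names(consensus_matrices)[i]]] <- F
    # area under the step CDF on [0, 1]
    xs <- c(0, v, 1)
    area[i] <- sum(diff(xs) * F(xs[-length(xs)]))
  }
  delta <- numeric(length(ks)); names(delta) <- names(area)
  delta[1] <- area[1]
  if (length(ks) > 1) {
    inc <- diff(area)
    prev <- area[-length(area)]
    # degenerate all-mass-at-1 matrices have area 0: no increase = no gain
    delta[-1] <- ifelse(prev > 0, inc / prev, ifelse(inc == 0, 0, Inf))
  }
  ok <- which(delta >= elbow_threshold)
  selected <- if (length(ok)) ks[max(ok)] else ks[1]
  list(cdf = cdf, area = area, delta_area = delta, selected_k = selected)
}

#' Per-cluster expression summary for a gene panel
#'
#' Medians per cluster and a Kruskal-Wallis test per gene. Genes absent
#' from the matrix are collected in the `skipped` attribute rather than
#' failing the call.
#'
#' @param expr genes x samples matrix.
#' @param partition named cluster labels covering the samples.
#' @param genes genes to summarize.
#' @return long data.frame (gene, cluster, median, plus per-gene `p`,
#'   `p_adj`); attribute `skipped` lists missing genes.
#' @export
cluster_expression_summary <- function(expr, partition, genes) {
  m <- .as_expr_values(expr)
  if (!is.null(names(partition))) partition <- partition[colnames(m)]
  if (length(partition) != ncol(m) || any(is.na(partition)))
    .stopf("partition must cover every expression sample")
  found <- intersect(genes, rownames(m))
  skipped <- setdiff(genes, found)
  cl <- as.character(partition)
  rows <- list(); pvals <- numeric(length(found)); names(pvals) <- found
  for (g in found) {
    byg <- split(m[g, ], cl)
    pvals[g] <- kruskal_wallis(byg)$p_value
    rows[[g]] <- data.frame(gene = g, cluster = names(byg),
                            median = vapply(byg, stats::median, numeric(1)),
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(out)) {
    out$p <- pvals[out$gene]
    adj <- bh_adjust(pvals)
    out$p_adj <- adj[out$gene]
  }
  structure(out, skipped = skipped)
}
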