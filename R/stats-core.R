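# Rank-based statistical primitives, correlation and multiplicity control.
# The rank tests delegate to base R's canonical implementations behind
# stable contracts; all p-values are two-sided.

.test_result <- function(statistic, p_value, df = NA_real_, n = NA_integer_,
                         method = "") {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 df = df, n = n, method = method), class = "m6a_test")
}

#' @export
print.m6a_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Kruskal-Wallis rank test
#'
#' H statistic with tie correction, p from chi-square(k - 1). When every
#' value is identical across all groups the test is degenerate by
#' construction and returns H = 0, p = 1 rather than an error.
#'
#' @param groups list of >= 2 numeric vectors, each non-empty, total n >= 3.
#' @return an `m6a_test` result.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) .stopf("need >= 2 groups")
  if (any(lengths(groups) < 1)) .stopf("every group needs >= 1 observation")
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) .stopf("total n must be >= 3")
  if (any(!is.finite(x))) .stopf("non-finite values")
  k <- length(groups)
  if (length(unique(x)) == 1)
    return(.test_result(0, 1, df = k - 1, n = length(x), method = "Kruskal-Wallis"))
  g <- factor(rep(seq_len(k), lengths(groups)))
  kt <- stats::kruskal.test(x, g)
  .test_result(kt$statistic, kt$p.value, df = unname(kt$parameter),
               n = length(x), method = "Kruskal-Wallis")
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided; exact enumeration for small tie-free samples (both n <= 25),
#' normal approximation with tie and continuity correction otherwise. The
#' statistic is U for the first sample.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param exact_max largest per-group n for which the exact distribution is
#'   used (when tie-free).
#' @return an `m6a_test` result.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25) {
  if (!length(x) || !length(y)) .stopf("empty group")
  if (any(!is.finite(c(x, y)))) .stopf("non-finite values")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact, correct = TRUE))
  .test_result(wt$statistic, min(1, wt$p.value), n = length(x) + length(y),
               method = if (use_exact) "Wilcoxon rank-sum (exact)"
                        else "Wilcoxon rank-sum (normal approx.)")
}

#' Spearman rank correlation
#'
#' rho on average ranks; two-sided p from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with n - 2 df.
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) .stopf("x and y lengths differ")
  n <- length(x)
  if (n < 3) .stopf("need n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y))) .stopf("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    .stopf("constant vector: Spearman rho undefined")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  list(rho = unname(rho), p_value = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotone enforcement; input order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    .stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Checkpoint-gene alias map
#'
#' Protein-style names resolve to the HGNC symbols used in expression
#' matrices: PD-1 -> PDCD1, PD-L1 -> CD274, CTLA-4 -> CTLA4.
#'
#' @return named character vector (alias -> symbol).
#' @export
gene_alias_map <- function() {
  c("PD-1" = "PDCD1", "PD1" = "PDCD1",
    "PD-L1" = "CD274", "PDL1" = "CD274",
    "CTLA-4" = "CTLA4", "CTLA4" = "CTLA4")
}

#' Resolve a gene symbol against an expression universe
#'
#' Returns the symbol itself when present, otherwise tries the checkpoint
#' alias map (case-insensitive).
#'
#' @param gene query symbol.
#' @param universe character vector of available symbols.
#' @return the resolved symbol, or `NA_character_` when unresolvable.
#' @export
resolve_gene <- function(gene, universe) {
  if (gene %in% universe) return(gene)
  amap <- gene_alias_map()
  hit <- amap[match(toupper(gene), toupper(names(amap)))]
  if (!is.na(hit) && hit %in% universe) return(unname(hit))
  NA_character_
}

#' Compare one gene's expression across sample groups
#'
#' Kruskal-Wallis for >= 3 groups, rank-sum for 2; the query may be a
#' checkpoint alias (PD-1, PD-L1, CTLA-4). Group medians are reported.
#'
#' @param expr genes x samples matrix.
#' @param gene gene symbol or alias.
#' @param groups factor/character vector of group labels, one per sample
#'   (aligned with `colnames(expr)`, or named by sample id).
#' @return list with `gene` (resolved), `test` (`m6a_test`) and `medians`.
#' @export
compare_gene_by_group <- function(expr, gene, groups) {
  m <- .as_expr_values(expr)
  sym <- resolve_gene(gene, rownames(m))
  if (is.na(sym)) {
    amap <- gene_alias_map()
    cand <- names(amap)[amap %in% rownames(m)]
    .stopf("gene '%s' not found; known aliases present: %s", gene,
           if (length(cand)) paste(unique(cand), collapse = ", ") else "none")
  }
  if (!is.null(names(groups))) groups <- groups[colnames(m)]
  if (length(groups) != ncol(m) || any(is.na(groups)))
    .stopf("groups must cover every sample")
  vals <- split(m[sym, ], as.character(groups))
  test <- if (length(vals) == 2) wilcoxon_rank_sum(vals[[1]], vals[[2]])
          else kruskal_wallis(vals)
  list(gene = sym, test = test,
       medians = vapply(vals, stats::median, numeric(1)))
}
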