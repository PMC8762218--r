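# Moderated-statistic DEG screening across clusters and univariate Cox
# filtering down to the prognosis-related gene panel.

# Invert the trigamma function by Newton iteration on 1/trigamma
# (monotone, nearly linear); used by the moment-matching variance prior.
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Moment-matching fit of the scaled inverse-chi-square variance prior
# (d0, s0^2) from per-gene sample variances s2 on df degrees of freedom:
# match mean and variance of log s2 via digamma/trigamma identities.
.fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) * (sum(ok) - 1) / sum(ok)
  evar <- evar - trigamma(df / 2)
  if (evar > 0) {
    d0 <- 2 * .trigamma_inverse(evar)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ebar)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated one-way ANOVA across clusters
#'
#' Per gene: group means by one-way linear model, residual variance `s2_g`
#' on `n - k` df, empirical-Bayes moderation
#' `s2~ = (d0 * s02 + df * s2_g) / (d0 + df)` with the prior `(d0, s02)`
#' estimated by moment matching on the log-variance distribution, then a
#' moderated F of the between-cluster means against `s2~` with
#' `(k - 1, d0 + df)` degrees of freedom. Genes with zero variance across
#' all samples are excluded (recorded in the `excluded` attribute).
#'
#' @param expr genes x samples matrix on the log2 scale.
#' @param partition named cluster labels covering the samples; >= 2
#'   clusters with >= 2 samples each.
#' @param d0,s02 optional prior overrides (for limit/diagnostic use; both
#'   must be supplied together).
#' @return data.frame per gene: `gene`, per-cluster `mean_*`, `F`, `p`,
#'   `p_adj`; attributes `d0`, `s02`, `df_residual`, `excluded`.
#' @export
moderated_anova <- function(expr, partition, d0 = NULL, s02 = NULL) {
  m <- .as_expr_values(expr)
  if (!is.null(names(partition))) partition <- partition[colnames(m)]
  if (length(partition) != ncol(m) || any(is.na(partition)))
    .stopf("partition must cover every expression sample")
  cl <- factor(as.character(partition))
  k <- nlevels(cl)
  n <- ncol(m)
  if (k < 2) .stopf("need >= 2 clusters")
  if (any(table(cl) < 2)) .stopf("every cluster needs >= 2 samples")
  df_resid <- n - k

  grp_idx <- split(seq_len(n), cl)
  gmeans <- vapply(grp_idx, function(ix) rowMeans(m[, ix, drop = FALSE]),
                   numeric(nrow(m)))
  sizes <- lengths(grp_idx)
  grand <- as.vector(gmeans %*% sizes) / n
  ssb <- as.vector(((gmeans - grand)^2) %*% sizes)
  sst <- rowSums((m - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  s2 <- ssw / df_resid
  excluded <- rownames(m)[sst == 0]
  if (length(excluded))
    .warnf("excluded %d zero-variance gene(s)", length(excluded))
  keep <- sst > 0

  if (is.null(d0) != is.null(s02)) .stopf("supply d0 and s02 together or neither")
  if (is.null(d0)) {
    prior <- .fit_variance_prior(s2[keep], df_resid)
    d0 <- prior$d0; s02 <- prior$s02
  }
  s2_mod <- if (is.infinite(d0)) rep(s02, sum(keep))
            else (d0 * s02 + df_resid * s2[keep]) / (d0 + df_resid)
  Fstat <- (ssb[keep] / (k - 1)) / s2_mod
  df2 <- if (is.infinite(d0)) Inf else d0 + df_resid
  p <- stats::pf(Fstat, k - 1, df2, lower.tail = FALSE)

  out <- data.frame(gene = rownames(m)[keep],
                    stats::setNames(as.data.frame(gmeans[keep, , drop = FALSE]),
                                    paste0("mean_", levels(cl))),
                    F = Fstat, p = p, p_adj = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, d0 = d0, s02 = s02, df_residual = df_resid, excluded = excluded)
}

#' Select differentially expressed genes
#'
#' Genes below the raw-p criterion (the screen's stated threshold is raw,
#' not adjusted; adjusted values remain in the result table for reference).
#'
#' @param result a [moderated_anova()] table.
#' @param p_threshold raw p-value criterion (default 1e-4).
#' @return character vector of gene symbols.
#' @export
select_degs <- function(result, p_threshold = 1e-4) {
  stopifnot(is.data.frame(result), all(c("gene", "p") %in% names(result)))
  result$gene[result$p < p_threshold]
}

#' Univariate Cox screen to the prognosis-related panel
#'
#' Per gene, a univariate proportional-hazards fit on its continuous
#' (log-scale) expression; genes with Wald p below the threshold form the
#' panel. Non-converged fits are dropped with a warning.
#'
#' @param expr genes x samples matrix (log2 scale).
#' @param clinical data.frame with `sample_id`, `os_time`, `os_event`.
#' @param genes candidate genes (e.g. the DEG list).
#' @param p_threshold Wald-p criterion (default 1e-3).
#' @return data.frame `gene`, `beta`, `HR` (= exp(beta)), `se`, `p` for the
#'   retained genes; attribute `tested` gives the full screen table.
#' @export
cox_screen <- function(expr, clinical, genes, p_threshold = 1e-3) {
  m <- .as_expr_values(expr)
  clinical <- validate_clinical(clinical)
  common <- intersect(colnames(m), clinical$sample_id)
  if (length(common) < 3) .stopf("too few samples shared by expression and clinical")
  cl <- clinical[match(common, clinical$sample_id), ]
  genes <- intersect(genes, rownames(m))
  if (!length(genes)) .stopf("no candidate gene present in expression")
  rows <- vector("list", length(genes))
  dropped <- character(0)
  for (i in seq_along(genes)) {
    g <- genes[i]
    xg <- m[g, common]
    if (stats::sd(xg) == 0) { dropped <- c(dropped, g); next }
    fit <- tryCatch(
      cox_fit(cl$os_time, cl$os_event, matrix(xg, dimnames = list(NULL, g))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { dropped <- c(dropped, g); next }
    rows[[i]] <- data.frame(gene = g, beta = fit$beta[1], HR = fit$HR[1],
                            se = fit$se[1], p = fit$p[1],
                            stringsAsFactors = FALSE)
  }
  if (length(dropped))
    .warnf("cox_screen dropped %d gene(s) (constant or non-converged)", length(dropped))
  tested <- do.call(rbind, rows)
  rownames(tested) <- NULL
  panel <- tested[!is.na(tested$p) & tested$p < p_threshold, , drop = FALSE]
  rownames(panel) <- NULL
  structure(panel, tested = tested, p_threshold = p_threshold)
}
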