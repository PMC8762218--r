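# Survival machinery: product-limit estimator, log-rank test, Cox
# proportional hazards (Newton-Raphson with Efron tie handling and
# step-halving), maximally-selected log-rank cutpoint, and IPCW
# time-dependent ROC/AUC.

.check_surv <- function(time, event) {
  if (length(time) != length(event)) .stopf("time and event lengths differ")
  if (any(!is.finite(time)) || any(time <= 0)) .stopf("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) .stopf("event must be 0 or 1")
}

#' Kaplan-Meier product-limit fit
#'
#' `S(t) = prod_(t_i <= t) (1 - d_i / n_i)` over distinct event times, with
#' Greenwood variance. A cohort with no events returns S = 1 everywhere
#' with a warning.
#'
#' @param time follow-up times > 0.
#' @param event 1 = death, 0 = censored.
#' @return a `km_curve` data.frame: `time`, `n_risk`, `n_event`, `surv`,
#'   `se` (Greenwood), one row per distinct event time.
#' @export
km_fit <- function(time, event) {
  .check_surv(time, event)
  if (sum(event) == 0) {
    warning("no events: survival curve is identically 1", call. = FALSE)
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0), se = numeric(0))
    class(out) <- c("km_curve", "data.frame")
    attr(out, "n") <- length(time)
    return(out)
  }
  et <- sort(unique(time[event == 1]))
  n_risk <- vapply(et, function(t) sum(time >= t), numeric(1))
  d <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - d / n_risk)
  gw <- cumsum(d / (n_risk * (n_risk - d)))
  se <- surv * sqrt(ifelse(is.finite(gw), gw, NA))
  out <- data.frame(time = et, n_risk = n_risk, n_event = d, surv = surv, se = se)
  class(out) <- c("km_curve", "data.frame")
  attr(out, "n") <- length(time)
  out
}

#' Evaluate a KM step function
#'
#' @param km a `km_curve`.
#' @param t evaluation times.
#' @param left use the left limit S(t-) (steps strictly before t).
#' @return survival probabilities.
#' @export
km_surv_at <- function(km, t, left = FALSE) {
  vapply(t, function(tt) {
    ix <- if (left) km$time < tt else km$time <= tt
    if (!any(ix)) 1 else km$surv[max(which(ix))]
  }, numeric(1))
}

# Two-group log-rank O-E and variance, returned unstandardized.
# Vectorized over tie blocks (hot path of the cutpoint search).
.logrank2 <- function(time, event, in_grp1) {
  o <- order(time)
  tt <- time[o]; ev <- event[o]; g1 <- in_grp1[o]
  n <- length(tt)
  block <- cumsum(!duplicated(tt)) # 1, 2, ... per distinct time
  starts <- which(!duplicated(tt))
  nrisk <- (n:1)[starts]
  n1risk <- rev(cumsum(rev(g1)))[starts]
  d <- as.vector(rowsum(ev, block))
  d1 <- as.vector(rowsum(ev * g1, block))
  keep <- d > 0
  nr <- nrisk[keep]; n1r <- n1risk[keep]; dd <- d[keep]; dd1 <- d1[keep]
  OE <- sum(dd1 - dd * n1r / nr)
  ok <- nr > 1
  V <- sum((dd * (nr - dd) / (nr - 1) * n1r * (nr - n1r) / nr^2)[ok])
  c(OE = OE, V = V)
}

#' Log-rank (Mantel-Haenszel) test across groups
#'
#' Observed-minus-expected event counts per group accumulated over distinct
#' event times with hypergeometric variance; chi-square statistic on g - 1
#' degrees of freedom.
#'
#' @param time,event survival data.
#' @param group group labels (>= 2 non-empty groups).
#' @return an `m6a_test` with additional fields `observed`, `expected` per
#'   group.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  group <- as.character(group)
  if (length(group) != length(time)) .stopf("group must cover every subject")
  lev <- sort(unique(group))
  g <- length(lev)
  if (g < 2) .stopf("need >= 2 groups")
  if (any(table(factor(group, lev)) == 0)) .stopf("empty group")
  et <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(g), lev)
  V <- matrix(0, g, g, dimnames = list(lev, lev))
  for (t in et) {
    at <- time >= t
    n <- sum(at)
    ng <- vapply(lev, function(l) sum(at & group == l), numeric(1))
    d <- sum(time == t & event == 1)
    dg <- vapply(lev, function(l) sum(time == t & event == 1 & group == l), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      mult <- d * (n - d) / (n - 1)
      V <- V + mult * (diag(ng, g) * n - outer(ng, ng)) / n^2
    }
  }
  x <- (O - E)[-g]
  Vs <- V[-g, -g, drop = FALSE]
  stat <- tryCatch(as.numeric(t(x) %*% solve(Vs, x)), error = function(e) 0)
  if (!is.finite(stat) || stat < 0) stat <- 0
  p <- stats::pchisq(stat, df = g - 1, lower.tail = FALSE)
  res <- .test_result(stat, p, df = g - 1, n = length(time), method = "log-rank")
  res$observed <- O
  res$expected <- E
  res
}

# Efron/Breslow partial log-likelihood, gradient and information at beta.
# Risk-set sums are precomputed as suffix sums over time-sorted subjects,
# so the remaining loop runs over distinct event times only.
.cox_llgh <- function(time, event, X, beta, efron = TRUE) {
  n <- nrow(X); p <- ncol(X)
  o <- order(time)
  tt <- time[o]; ev <- event[o]
  Xo <- X[o, , drop = FALSE]
  eta <- as.vector(Xo %*% beta)
  w <- exp(eta)
  wx <- Xo * w
  rcs <- function(v) rev(cumsum(rev(v)))
  cum0 <- rcs(w)
  cum1 <- apply(wx, 2, rcs)
  if (p == 1) dim(cum1) <- c(n, 1)
  # suffix sums of w * x_j * x_k for the upper triangle
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  cum2 <- matrix(0, n, nrow(pairs))
  for (q in seq_len(nrow(pairs)))
    cum2[, q] <- rcs(wx[, pairs[q, 1]] * Xo[, pairs[q, 2]])
  starts <- which(!duplicated(tt))
  block <- cumsum(!duplicated(tt))
  die <- which(ev == 1)
  db <- block[die]
  # per-death-block tie sums (rowsum returns blocks in sorted order)
  s0d <- as.vector(rowsum(w[die], db))
  s1d <- rowsum(wx[die, , drop = FALSE], db)
  tied_cross <- wx[die, pairs[, 1], drop = FALSE] * Xo[die, pairs[, 2], drop = FALSE]
  s2d <- rowsum(tied_cross, db)
  ublocks <- sort(unique(db))
  d_b <- as.vector(table(db))
  i0 <- starts[ublocks]
  # expand each block into its Efron death slots l = 0..d-1
  ridx <- rep(seq_along(ublocks), d_b)
  f <- if (efron) unlist(lapply(d_b, function(d) (seq_len(d) - 1) / d))
       else numeric(sum(d_b))
  den0 <- cum0[i0][ridx] - f * s0d[ridx]
  Mu <- (cum1[i0, , drop = FALSE][ridx, , drop = FALSE] -
           f * s1d[ridx, , drop = FALSE]) / den0
  ll <- sum(eta[die]) - sum(log(den0))
  grad <- colSums(Xo[die, , drop = FALSE]) - colSums(Mu)
  num2 <- (cum2[i0, , drop = FALSE][ridx, , drop = FALSE] -
             f * s2d[ridx, , drop = FALSE]) / den0
  S2sum <- matrix(0, p, p)
  cs2 <- colSums(num2)
  S2sum[cbind(pairs[, 1], pairs[, 2])] <- cs2
  S2sum[cbind(pairs[, 2], pairs[, 1])] <- cs2
  info <- S2sum - crossprod(Mu)
  list(ll = ll, grad = grad, info = info)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood with Efron tie
#' handling (Breslow available), step-halving so the log partial
#' likelihood never decreases, Wald standard errors from the inverse
#' information, and 95% CIs on the log-hazard scale.
#'
#' @param time,event survival data.
#' @param covariates numeric matrix or data.frame, n x p, no constant
#'   column; factors/characters are not auto-expanded (convert first).
#' @param tie_method `"efron"` or `"breslow"`.
#' @param max_iter,tol Newton control.
#' @return a `cox_fit` list: `beta`, `se`, `HR`, `ci_lower`, `ci_upper`,
#'   `z`, `p`, `loglik` (final), `loglik_null`, `loglik_trace`, `vcov`,
#'   `converged`, `n`, `n_event`, `tie_method`.
#' @export
cox_fit <- function(time, event, covariates, tie_method = c("efron", "breslow"),
                    max_iter = 25, tol = 1e-9) {
  tie_method <- match.arg(tie_method)
  .check_surv(time, event)
  X <- as.matrix(covariates)
  if (!is.numeric(X)) .stopf("covariates must be numeric")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(time)) .stopf("covariate rows must match subjects")
  if (nrow(X) <= ncol(X)) .stopf("need n > number of covariates")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const)) .stopf("constant covariate(s): %s",
                         paste(colnames(X)[const], collapse = ", "))
  if (sum(event) == 0) .stopf("no events: partial likelihood is flat")
  efron <- tie_method == "efron"
  # center covariates for numerical stability; beta is unaffected
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  p <- ncol(Xc)
  beta <- numeric(p)
  cur <- .cox_llgh(time, event, Xc, beta, efron)
  trace <- cur$ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) break
    new_beta <- beta + step
    nxt <- .cox_llgh(time, event, Xc, new_beta, efron)
    halvings <- 0
    while (nxt$ll < cur$ll && halvings < 20) { # step-halving: ll never decreases
      step <- step / 2
      new_beta <- beta + step
      nxt <- .cox_llgh(time, event, Xc, new_beta, efron)
      halvings <- halvings + 1
    }
    delta <- nxt$ll - cur$ll
    beta <- new_beta
    cur <- nxt
    trace <- c(trace, cur$ll)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    .warnf("cox_fit did not converge in %d iterations", max_iter)
  if (any(abs(beta) > 20))
    .warnf("cox_fit: |beta| > 20 suggests separation")
  vcov <- tryCatch(solve(cur$info), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcov), 0))
  z <- beta / se
  null_ll <- .cox_llgh(time, event, Xc, numeric(p), efron)$ll
  structure(list(
    beta = stats::setNames(beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    HR = stats::setNames(exp(beta), colnames(X)),
    ci_lower = stats::setNames(exp(beta - 1.96 * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + 1.96 * se), colnames(X)),
    z = z, p = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    loglik = cur$ll, loglik_null = null_ll, loglik_trace = trace,
    vcov = vcov, converged = converged, n = length(time),
    n_event = sum(event), tie_method = tie_method
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s%s\n", x$n, x$n_event,
              x$tie_method, if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(beta = x$beta, HR = x$HR, lo95 = x$ci_lower,
                   hi95 = x$ci_upper, p = x$p))
  invisible(x)
}

#' Forest-plot-ready table from a Cox fit
#' @param fit a `cox_fit`.
#' @return data.frame `term`, `beta`, `HR`, `lo95`, `hi95`, `p`.
#' @export
cox_table <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  data.frame(term = names(fit$beta), beta = unname(fit$beta),
             HR = unname(fit$HR), lo95 = unname(fit$ci_lower),
             hi95 = unname(fit$ci_upper), p = unname(fit$p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic
#' `|O - E| / sqrt(V)` at every observed marker value whose low
#' (`marker <= c`) and high (`marker > c`) groups both hold at least
#' `minprop` of the cohort, and returns the maximizing cutoff. The naive
#' p-value ignores the selection; an optional permutation p (marker
#' permuted, maximum re-selected) corrects for it.
#'
#' @param marker continuous per-subject marker.
#' @param time,event survival data.
#' @param minprop minimum group proportion on each side.
#' @param n_perm permutations for the selection-corrected p (0 = skip).
#' @param seed seed for the permutations.
#' @return a `cutpoint_result` list: `cutoff`, `statistic` (standardized),
#'   `n_low`, `n_high`, `minprop`, `p_naive`, `p_perm` (NA when skipped).
#' @export
optimal_cutpoint <- function(marker, time, event, minprop = 0.1,
                             n_perm = 0, seed = 1) {
  .check_surv(time, event)
  if (length(marker) != length(time)) .stopf("marker must cover every subject")
  if (any(!is.finite(marker))) .stopf("marker must be finite")
  n <- length(marker)
  min_n <- max(1L, ceiling(minprop * n))
  max_z <- function(mk) {
    cand <- sort(unique(mk))
    best <- c(z = -Inf, cut = NA_real_)
    for (c in cand) {
      lo <- mk <= c
      if (sum(lo) < min_n || sum(!lo) < min_n) next
      lr <- .logrank2(time, event, lo)
      if (lr["V"] <= 0) next
      z <- abs(lr["OE"]) / sqrt(lr["V"])
      if (z > best["z"]) best <- c(z = unname(z), cut = c)
    }
    best
  }
  obs <- max_z(marker)
  if (!is.finite(obs["z"]))
    .stopf("no admissible cutoff at minprop = %g", minprop)
  p_perm <- NA_real_
  if (n_perm > 0) {
    set.seed(m6a_seed(seed, 97L))
    exceed <- 0
    for (b in seq_len(n_perm)) {
      zb <- max_z(sample(marker))["z"]
      if (is.finite(zb) && zb >= obs["z"]) exceed <- exceed + 1
    }
    p_perm <- (1 + exceed) / (n_perm + 1)
  }
  structure(list(cutoff = unname(obs["cut"]), statistic = unname(obs["z"]),
                 n_low = sum(marker <= obs["cut"]),
                 n_high = sum(marker > obs["cut"]), minprop = minprop,
                 p_naive = 2 * stats::pnorm(-unname(obs["z"])),
                 p_perm = p_perm),
            class = "cutpoint_result")
}

#' IPCW time-dependent AUC (cumulative cases / dynamic controls)
#'
#' At horizon t, cases are subjects with an event by t and controls those
#' still at risk beyond t. Concordance between the marker (higher = higher
#' risk) and case status is weighted by the inverse probability of
#' censoring: cases by `1 / G(T_i-)`, controls by `1 / G(t)`, with G the
#' Kaplan-Meier estimate of the censoring distribution. With no censoring
#' all weights are 1 and the estimate equals the plain concordance
#' fraction. Horizons beyond follow-up, or with no case or no control, are
#' dropped with a warning.
#'
#' @param marker risk marker.
#' @param time,event survival data (time in days).
#' @param horizons_years evaluation horizons in years.
#' @param days_per_year year-to-day conversion (365.25).
#' @return data.frame: `horizon_years`, `horizon_days`, `auc` (as-is,
#'   higher marker = higher risk), `auc_oriented` (flipped when the mean
#'   AUC is below 0.5), `n_case`, `n_control`; attribute `flipped`.
#' @export
td_auc <- function(marker, time, event, horizons_years = c(1, 2, 3, 4),
                   days_per_year = 365.25) {
  .check_surv(time, event)
  if (length(marker) != length(time)) .stopf("marker must cover every subject")
  horizons <- horizons_years * days_per_year
  cens_km <- suppressWarnings(km_fit(time, 1 - event))
  G_at <- function(t, left = FALSE) km_surv_at(cens_km, t, left = left)
  rows <- list()
  for (h in seq_along(horizons)) {
    t0 <- horizons[h]
    is_case <- time <= t0 & event == 1
    is_ctrl <- time > t0
    Gt <- G_at(t0)
    if (!any(is_case) || !any(is_ctrl) || Gt <= 0) {
      .warnf("horizon %g years dropped (no cases, no controls, or beyond follow-up)",
             horizons_years[h])
      next
    }
    wc <- 1 / G_at(time[is_case], left = TRUE)
    ok <- is.finite(wc) & wc > 0
    mc <- marker[is_case][ok]; wc <- wc[ok]
    mk <- marker[is_ctrl]
    wctrl <- rep(1 / Gt, length(mk))
    cmp <- outer(mc, mk, function(a, b) (a > b) + 0.5 * (a == b))
    wgt <- outer(wc, wctrl)
    auc <- sum(cmp * wgt) / sum(wgt)
    rows[[length(rows) + 1]] <- data.frame(
      horizon_years = horizons_years[h], horizon_days = t0, auc = auc,
      n_case = sum(is_case), n_control = sum(is_ctrl))
  }
  if (!length(rows)) .stopf("no usable horizon")
  out <- do.call(rbind, rows)
  flipped <- mean(out$auc) < 0.5
  out$auc_oriented <- if (flipped) 1 - out$auc else out$auc
  structure(out, flipped = flipped)
}

#' KM curves, global and pairwise log-rank across groups
#'
#' @param time,event survival data.
#' @param labels group labels covering every subject.
#' @return list: `curves` (named `km_curve` list), `global` (`m6a_test`),
#'   `pairwise` (data.frame group_a, group_b, p, p_adj over the
#'   g(g-1)/2 pairs).
#' @export
survival_by_groups <- function(time, event, labels) {
  .check_surv(time, event)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  curves <- lapply(lev, function(l) suppressWarnings(
    km_fit(time[labels == l], event[labels == l])))
  names(curves) <- lev
  global <- logrank_test(time, event, labels)
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                   p = apply(pairs, 2, function(pr) {
                     ix <- labels %in% pr
                     logrank_test(time[ix], event[ix], labels[ix])$p_value
                   }), stringsAsFactors = FALSE)
  pw$p_adj <- bh_adjust(pw$p)
  list(curves = curves, global = global, pairwise = pw)
}
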