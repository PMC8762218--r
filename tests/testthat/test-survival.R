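test_that("km_fit reproduces the hand product-limit fixture", {
  km <- km_fit(c(1, 2, 3, 4), c(1, 1, 0, 1))
  # steps: 3/4, then 2/3 of that, censor at 3, then 0/1 at t = 4
  expect_equal(km$time, c(1, 2, 4))
  expect_equal(km$surv, c(3 / 4, 1 / 2, 0))
  expect_equal(km$n_risk, c(4, 3, 1))
  expect_equal(km$n_event, c(1, 1, 1))
  # step heights are exactly d_i / n_i
  expect_equal(km$surv, cumprod(1 - km$n_event / km$n_risk))
})

test_that("km_fit handles no events and matches survfit on random data", {
  expect_warning(km0 <- km_fit(c(5, 7, 9), c(0, 0, 0)), "no events")
  expect_equal(nrow(km0), 0L)
  expect_equal(km_surv_at(km0, c(1, 100)), c(1, 1))
  skip_if_not_installed("survival")
  set.seed(50)
  t <- round(rexp(80, 0.01)) + 1; ev <- rbinom(80, 1, 0.6)
  km <- km_fit(t, ev)
  sf <- survival::survfit(survival::Surv(t, ev) ~ 1)
  ix <- sf$n.event > 0
  expect_equal(km$surv, sf$surv[ix], tolerance = 1e-12)
  expect_equal(km$se[-nrow(km)],
               (sf$std.err * sf$surv)[ix][-nrow(km)], tolerance = 1e-9)
})

test_that("km_fit is invariant to time-unit rescaling", {
  set.seed(51)
  t <- rexp(40, 0.01); ev <- rbinom(40, 1, 0.7)
  a <- km_fit(t, ev)
  b <- km_fit(t / 30.4375, ev) # days -> months
  expect_equal(b$surv, a$surv)
  expect_equal(b$time * 30.4375, a$time)
})

test_that("logrank_test matches the hand hypergeometric enumeration", {
  # subjects: times 1,2,3 all events, groups A,B,A
  # t=1: O_A=1 E_A=2/3 V=2/9; t=2: O_A=0 E_A=1/2 V=1/4; t=3: n=1 no variance
  # chi2 = (1/6)^2 / (17/36) = 1/17
  r <- logrank_test(c(1, 2, 3), c(1, 1, 1), c("A", "B", "A"))
  expect_equal(r$statistic, 1 / 17, tolerance = 1e-12)
  expect_equal(unname(r$observed["A"]), 2)
  expect_equal(unname(r$expected["A"]), 2 / 3 + 1 / 2 + 1, tolerance = 1e-12)
  # identical duplicated groups: exact symmetry
  t2 <- c(1, 3, 5, 8); e2 <- c(1, 0, 1, 1)
  r2 <- logrank_test(c(t2, t2), c(e2, e2), rep(c("x", "y"), each = 4))
  expect_equal(r2$statistic, 0, tolerance = 1e-12)
  expect_equal(r2$p_value, 1)
})

test_that("logrank_test agrees with survdiff across 2 and 3 groups", {
  skip_if_not_installed("survival")
  set.seed(52)
  t <- round(rexp(90, 0.01)) + 1; ev <- rbinom(90, 1, 0.7)
  g2 <- sample(c("a", "b"), 90, TRUE)
  g3 <- sample(c("a", "b", "c"), 90, TRUE)
  expect_equal(logrank_test(t, ev, g2)$statistic,
               survival::survdiff(survival::Surv(t, ev) ~ g2)$chisq,
               tolerance = 1e-10)
  expect_equal(logrank_test(t, ev, g3)$statistic,
               survival::survdiff(survival::Surv(t, ev) ~ g3)$chisq,
               tolerance = 1e-10)
  expect_error(logrank_test(t, ev, rep("only", 90)), ">= 2 groups")
})

test_that("cox_fit matches coxph for Efron and Breslow ties", {
  skip_if_not_installed("survival")
  set.seed(53)
  n <- 100
  x1 <- rnorm(n); x2 <- rbinom(n, 1, 0.4)
  t <- round(rexp(n, 0.01 * exp(0.6 * x1 - 0.4 * x2))) + 1 # heavy ties
  ev <- rbinom(n, 1, 0.7)
  for (ties in c("efron", "breslow")) {
    mine <- cox_fit(t, ev, cbind(x1 = x1, x2 = x2), tie_method = ties)
    ref <- survival::coxph(survival::Surv(t, ev) ~ x1 + x2, ties = ties)
    expect_equal(unname(mine$beta), unname(stats::coef(ref)), tolerance = 1e-8)
    expect_equal(unname(mine$se), unname(sqrt(diag(stats::vcov(ref)))),
                 tolerance = 1e-8)
    expect_equal(mine$loglik, ref$loglik[2], tolerance = 1e-8)
    expect_equal(mine$loglik_null, ref$loglik[1], tolerance = 1e-8)
  }
})

test_that("cox_fit invariants: monotone likelihood, tie-free equivalence, Wald CIs", {
  set.seed(54)
  n <- 80
  x <- rnorm(n)
  t <- rexp(n, 0.01 * exp(0.5 * x)) # continuous: no ties
  ev <- rbinom(n, 1, 0.8)
  fe <- cox_fit(t, ev, matrix(x, dimnames = list(NULL, "x")))
  fb <- cox_fit(t, ev, matrix(x, dimnames = list(NULL, "x")), tie_method = "breslow")
  expect_false(is.unsorted(fe$loglik_trace))
  expect_equal(fe$beta, fb$beta, tolerance = 1e-10)
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-10)
  expect_equal(unname(fe$ci_lower), unname(exp(fe$beta - 1.96 * fe$se)))
  expect_true(all(fe$HR > 0))
  expect_error(cox_fit(t, ev, matrix(1, n, 1)), "constant")
  expect_error(cox_fit(t, rep(0, n), matrix(x)), "no events")
})

test_that("optimal_cutpoint finds a planted hazard change point", {
  set.seed(55)
  n <- 120
  marker <- c(runif(n / 2, 0, 1), runif(n / 2, 2, 3)) # gap at (1, 2)
  risk <- rep(c(0, 1.5), each = n / 2)
  t <- rexp(n, 0.005 * exp(risk)); ev <- rbinom(n, 1, 0.8)
  cp <- optimal_cutpoint(marker, t, ev)
  expect_gte(cp$cutoff, max(marker[1:(n / 2)]) - 1e-12)
  expect_lt(cp$cutoff, min(marker[(n / 2 + 1):n]))
  expect_gte(cp$n_low, ceiling(0.1 * n))
  expect_gte(cp$n_high, ceiling(0.1 * n))
})

test_that("cutpoint selection on noise is anti-conservative; permutation p corrects", {
  set.seed(56)
  n <- 60
  t <- rexp(n, 0.005); ev <- rbinom(n, 1, 0.7)
  cp <- optimal_cutpoint(rnorm(n), t, ev, n_perm = 40, seed = 2)
  expect_gte(cp$p_perm, cp$p_naive) # naive p ignores the maximal selection
  expect_error(optimal_cutpoint(rnorm(5), rexp(5), rep(1, 5), minprop = 0.5),
               "admissible")
})

test_that("td_auc is perfect for an oracle marker and exact without censoring", {
  # all events; marker = event time order: higher marker = later death
  t <- (1:20) * 50; ev <- rep(1, 20)
  a <- td_auc(t, t, ev, horizons_years = 1)
  expect_equal(a$auc, 0)          # anti-risk before orientation
  expect_equal(a$auc_oriented, 1) # perfect after
  expect_true(attr(a, "flipped"))
  set.seed(57)
  m <- rnorm(25); t2 <- sample(100:2000, 25); ev2 <- rep(1, 25)
  a2 <- suppressWarnings(td_auc(m, t2, ev2, horizons_years = c(1, 3)))
  for (i in seq_len(nrow(a2)))
    expect_equal(a2$auc[i], oracle_concordance(m, t2, a2$horizon_days[i]))
})

test_that("td_auc drops unusable horizons with a warning", {
  set.seed(58)
  t <- runif(30, 30, 300); ev <- rbinom(30, 1, 0.8) # nobody past 1 year
  expect_warning(a <- td_auc(rnorm(30), t, ev, horizons_years = c(0.5, 4)),
                 "dropped")
  expect_equal(a$horizon_years, 0.5)
})

test_that("survival_by_groups returns curves, global and pairwise tests", {
  co <- cached_cohort(n_samples = 120, seed = 5)
  part <- truth_partition(co)[co$clinical$sample_id]
  sv <- survival_by_groups(co$clinical$os_time, co$clinical$os_event, part)
  expect_named(sv$curves, c("A", "B", "C"))
  expect_equal(nrow(sv$pairwise), 3) # g(g-1)/2
  # planted: B = highest hazard, A = lowest; compare KM at median follow-up
  tmed <- stats::median(co$clinical$os_time)
  sA <- km_surv_at(sv$curves$A, tmed); sB <- km_surv_at(sv$curves$B, tmed)
  expect_gt(sA, sB)
  expect_lt(sv$global$p_value, 0.05)
})
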