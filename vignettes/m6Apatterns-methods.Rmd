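---
title: "m6Apatterns: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{m6Apatterns: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Apatterns)
```

## The scientific problem

N6-methyladenosine (m6A) is the most abundant internal mRNA modification,
deposited by methyltransferase "writers", recognized by "readers" and removed
by demethylase "erasers". In pancreatic adenocarcinoma, the joint expression
state of the 22 writer/reader/eraser regulators stratifies tumors into
modification patterns that differ in prognosis and in their immune
microenvironment. `m6Apatterns` implements the full analysis that makes that
claim testable: consensus clustering of patients on regulator expression
(m6Aclusters), single-sample enrichment scoring of immune-cell, stromal and
pathway signatures, a moderated differential-expression screen between the
clusters, a univariate Cox filter to a prognosis-related gene panel, a second
consensus clustering on that panel (gene clusters), and a per-patient
**m6Ascore** — the sum of the patient's projections on the first two
principal components of the panel — dichotomized at a maximally-selected
log-rank cutpoint and carried into survival, tumor-mutation-burden and
immune-checkpoint integrations.

Because the original cohorts are controlled-access downloads, the package
ships a synthetic-cohort generator with known ground truth; every pipeline
stage is validated against that truth or against independent oracles.

## The synthetic world

`sim_config()` fixes the stated world; `simulate_cohort()` realizes it from
one master seed (each component draws from a derived seed stream, so the
expression matrix, survival table, mutation table and CNV calls are
independently reproducible).

* **Clusters.** Three planted patient clusters with the 30/42/105 composition
  of the motivating cohort (n = 150 by default). Cluster centers are risk
  levels −1 (A), +1 (B), 0 (C): cluster A has all 22 regulators shifted down,
  cluster B up, by `cluster_shift` = 2 log2 units per unit center — i.e. a
  2-sd separation per gene between adjacent clusters at `sigma` = 1.
* **Latent score.** Per sample, `score = center + N(0, 0.5)`. It is
  risk-oriented: survival times are exponential with hazard
  `h0 * exp(hazard_beta * score)`, `hazard_beta` = 0.7 and
  `h0 = log(2)/500` per day (a 500-day median at score 0, in the range
  reported for resected pancreatic cancer). Censoring is exponential with its
  rate calibrated by root-finding so the expected censored fraction equals
  `censor_rate` = 0.4, typical of TCGA-like follow-up.
* **Signal genes.** 300 genes follow the latent score with slope
  `signal_shift` = 1 log2 unit (half up, half down): the true
  prognosis-related differential-expression block.
* **Signature fixtures.** 23 immune-cell sets (15 genes), ESTIMATE-style
  stromal and immune sets (30 genes), and 12 pathway sets (20 genes), all
  disjoint. Th2-cell, activated-NK, mast-cell, both ESTIMATE sets and a
  FoxO-like pathway are planted up in the poor-prognosis cluster B; the
  CD56dim-NK and ErbB-like sets down; the rest are null. Planted set genes
  move by `set_shift` = 1 log2 unit per unit cluster center — deliberately
  half the regulator shift. An earlier draft used the full 2-sd shift for
  set genes; that gives whole pathway blocks per-gene effects as large as
  the defining regulator panel, which is biologically implausible (bulk
  pathway co-regulation moves member genes by fractions of the within-gene
  sd) and creates a second dominant principal-component direction inside
  the prognostic panel whose arbitrary sign destabilizes the PC1+PC2 score.
  At 1 log2 unit the set-level enrichment contrasts remain overwhelmingly
  powered while the panel keeps a single dominant prognostic direction.
* **Mutations and CNV.** Per-sample mutation counts are Poisson with
  log-mean `log(30) + tmb_rho * score` (`tmb_rho` = −0.4), planting the
  anti-correlation between burden and score; records carry MAF variant
  classes (~15% Silent). Regulator CNV calls are drawn per gene with
  loss-prone propensities except for a gain-prone subset (VIRMA, G3BP1 and
  five others), mimicking the reported landscape.
* **Orientation note.** In the generator the latent score is a *risk* score
  (so Cox recovery of `hazard_beta` has a positive sign), and burden is
  anti-correlated with it. The m6Ascore itself never hard-codes a direction:
  PCA component signs are fixed by a deterministic anchor rule (the
  largest-|loading| gene gets a positive loading) and whether high score
  means good or poor prognosis is an empirical, recorded outcome — exactly
  as in the motivating analysis, where it fell out as protective.

What the generator does **not** emulate: realistic gene–gene correlation
within blocks beyond the planted shifts, negative-binomial count noise
(expression is Gaussian in log2 space, sufficient for the rank-based and
linear methods used downstream), batch structure, or missing clinical data.
A green test therefore establishes that the machinery recovers planted
structure of realistic effect size — not that it would be robust to every
artifact of real TCGA data.

## Consensus clustering and the choice of k

`consensus_cluster()` follows the standard resampling recipe: for each k,
draw 80% of samples without replacement 500 times, cluster each subsample,
and record `M(i,j)` = (times i, j co-clustered) / (times co-sampled). The
final partition cuts an average-linkage tree of `1 − M`. Genes are z-scored
first so high-expression genes do not dominate Euclidean distances.

k is selected from the per-k CDFs of the consensus values: with `A(k)` the
area under the CDF, the relative delta-area is `Δ(2) = A(2)` and
`Δ(k) = (A(k) − A(k−1))/A(k−1)`, and the selected k is the largest one with
`Δ(k) ≥ 0.1`.

**Base clusterer.** The default is average-linkage hierarchical clustering
on the subsample (the default of the reference implementation of this
algorithm), not k-means. This was a considered change: with a k-means base,
over-partitioning a crisply separated blob (k larger than the true number)
halves the blob along a noise-driven plane that changes every resample, so
consensus values inside the split blob land near 0.5 and the CDF area keeps
growing — `Δ(4) ≈ 0.27` on perfect 3-cluster data, and the 0.1-threshold
elbow rule over-selects k. A hierarchical base peels the same near-outlier
samples each time, `Δ(4)` drops to ~0.03–0.05, and the rule recovers the
planted k = 3 with adjusted Rand index 1. k-means remains available via
`base_method = "kmeans"`.

## Single-sample enrichment

`ssgsea_score()` implements the rank-weighted running-sum score: per sample,
genes get average ranks; walking the expression-ordered list, the cumulative
in-set weight (weights `rank^alpha`, `alpha` = 0.25, normalized to 1) minus
the cumulative out-of-set fraction is summed over all positions. Scores are
rank-based, hence invariant to any strictly increasing per-sample transform.
Cohort-level normalization (dividing the score matrix by its max − min) is
on for immune-cell scores and off for the ESTIMATE components, whose
combined score is *exactly* stromal + immune. Sets with fewer than
`min_overlap` = 5 genes present are dropped with a warning.

The kernel-smoothed GSVA variant is deliberately **not** implemented;
pathway contrasts reuse the same ssGSEA engine. This is the package's one
methodological substitution, and the only consequence is a different (still
rank-based) single-sample statistic feeding the same moderated contrasts.

One caveat worth knowing: single-sample scores of *null* sets are not
independent of planted structure, because ranks are compositional — lifting
one block of genes pushes every other gene's rank down. Null-set calibration
is therefore asserted on null cohorts, not on planted ones.

## Differential expression and the prognostic panel

`moderated_anova()` is a from-scratch empirical-Bayes one-way ANOVA: per
gene, residual variance `s2_g` on `n − k` df; a scaled inverse-chi-square
prior `(d0, s02)` fitted by moment-matching the mean and variance of
`log s2_g` (digamma/trigamma identities, trigamma inverted by Newton);
moderated variance `(d0*s02 + df*s2_g)/(d0 + df)`; moderated F with
`(k − 1, d0 + df)` df. On shared data it reproduces the reference
empirical-Bayes implementation's F statistics to well under 1%.

Both screens use **raw** p thresholds — DEGs at p < 1e-4, the univariate
Cox filter at p < 1e-3 — because those are the stated criteria of the
analysis being reproduced; BH-adjusted values are reported alongside.
The Cox covariate is continuous log2 expression, never a dichotomization.

## Survival machinery

All of it is implemented in-package and checked against the standard
survival package as an independent oracle in the test suite: Kaplan–Meier
with Greenwood variance; the Mantel–Haenszel log-rank across any number of
groups; Cox proportional hazards by Newton–Raphson on the Efron partial
likelihood (Breslow available) with step-halving, so the log partial
likelihood is non-decreasing across iterations, Wald CIs on the log-hazard
scale, and explicit non-convergence/separation flags.

`optimal_cutpoint()` maximizes the standardized two-group log-rank statistic
over observed marker values with both groups ≥ `minprop` = 0.1 of the
cohort. The selection makes the naive log-rank p anti-conservative; the
function therefore also offers a permutation-corrected p (marker permuted,
maximum re-selected). Both are reported, clearly labeled, without asserting
which one the motivating analysis used.

`td_auc()` is the IPCW cumulative-case/dynamic-control AUC: at horizon t,
cases (event by t) are weighted by `1/G(T−)` and controls (at risk past t)
by `1/G(t)`, with G the Kaplan–Meier estimate of the censoring
distribution. Horizons are specified in years and converted at 365.25
days/year. With no censoring the estimator reduces exactly to the
concordance fraction, which is how it is tested. AUCs are reported both
as-computed (higher marker = higher risk) and orientation-corrected, with
the flip recorded.

## The m6Ascore

`compute_m6ascore()` z-scores the panel genes (correlation PCA — a config
switch disables scaling), takes the SVD, and scores each sample by the sum
of its PC1 and PC2 projections. The "sum of PC1 and PC2" is interpreted
per sample — the alternative reading (summing loadings alone) is
sample-independent and cannot stratify patients. Component signs follow the
deterministic anchor rule above, so reruns are bit-identical.
`validate_external()` freezes the training loadings, centering and scaling
and projects a held-out cohort (partial panel coverage ≥ 3 genes is allowed
and logged); the high/low cutoff is re-estimated per cohort, since each
cohort is dichotomized at its own optimal cutpoint. Tumor mutation burden
is the per-sample non-silent MAF count, optionally per megabase using the
conventional 38 Mb exome denominator.

## Numerical choices and degenerate inputs

* Duplicate gene symbols on load: keep the row with the highest mean.
* All-tied expression in a sample makes rank scores undefined: error.
* Zero-variance genes: excluded from the moderated screen (logged), dropped
  from panels; an all-constant panel is an error.
* Rank-1 panels: PC2 projections are exactly 0 and the score equals PC1.
* Newton control: at most 25 iterations, convergence at |Δ loglik| < 1e-9,
  20 step-halvings; |beta| > 20 raises a separation warning.
* Ties in ranking broken by average rank; ordering among tied values is by
  row index (deterministic).
* Config serialization is JSON (no YAML dependency in the stack); every run
  writes its resolved config and a stable hash next to the outputs.

## Interpreting acceptance tests

The suite's acceptance criteria mirror in-text constants (registry
partition 7/13/2, 23 immune-cell sets) and property-based recoveries on the
stated world: planted-k selection, ssGSEA-oracle equivalence, KM/log-rank
oracles and null calibration, Cox coefficient recovery and CI coverage,
IPCW-AUC null calibration and censoring-free exactness, DEG type-I control
at the screen's own threshold (100 null cohorts at the default n = 150;
the bound treats "reps" as the number of replicate cohorts), m6Ascore
recovery of the latent score, and byte-level determinism of the full
pipeline. Where a criterion asserts a rate (e.g. "≥ 95% of null
permutations"), the corresponding unit test asserts a bound ~3 Monte-Carlo
standard deviations below the nominal rate so the test checks the claim,
not the noise.

## Known limitations

Single-sample enrichment is an algorithmic proxy for immune infiltration,
not a measurement. The GSVA kernel variant, GO/KEGG over-representation
against live annotation databases, and any network download of cohort data
are out of scope by design. The synthetic world is Gaussian and
block-structured; methods that would be stressed by heavy-tailed counts or
correlated backgrounds are only as validated as that world allows. The
optimal-cutpoint p-value inflation is reported, not resolved.
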