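# m6Apatterns

Quantifying N6-methyladenosine (m6A) modification patterns in bulk tumor
transcriptomes — built for pancreatic adenocarcinoma cohorts — and scoring
their prognostic and immune consequences per patient.

m6A, the most abundant internal mRNA modification, is controlled by 22
regulator genes: 7 methyltransferase *writers*, 13 binding-protein
*readers*, 2 demethylase *erasers*. Their joint expression state
stratifies tumors into modification patterns that differ in survival and
in immune/stromal infiltration. This package implements that analysis as a
tested, reusable pipeline for anyone with a gene × sample expression
matrix, a clinical table, and (optionally) MAF mutations and CNV calls:

1. **Regulator registry and variation summaries** — the curated 22-gene
   panel; CNV gain/loss frequencies; non-silent mutation frequency.
2. **Consensus clustering** (resampled, CDF/delta-area selection of k) on
   regulator expression → *m6Aclusters*, and later on the prognostic gene
   panel → *gene clusters*.
3. **Single-sample enrichment** — ssGSEA scores for 23 immune-cell
   signatures and pathway sets; ESTIMATE-style stromal/immune/combined
   scores (combined = stromal + immune, exactly).
4. **Differential screens** — empirical-Bayes moderated one-way ANOVA
   across clusters (DEGs at raw p < 1e-4), then univariate Cox filtering
   (p < 1e-3) to the prognosis-related panel.
5. **The m6Ascore** — per sample, the sum of its projections on the first
   two principal components of the panel:
   `m6Ascore_s = PC1_s + PC2_s`, dichotomized at the maximally selected
   log-rank cutpoint.
6. **Downstream integrations** — Kaplan–Meier/log-rank, uni/multivariate
   Cox (Efron ties, Newton–Raphson with step-halving), IPCW time-dependent
   AUC at 1–4 years, tumor-mutation-burden correlation and joint
   TMB × score survival strata, the regulator correlation/prognosis
   network, and the cluster→cluster→score attribute flow table.

A synthetic-cohort generator (`simulate_cohort()`) plants known clusters, a
latent hazard score, score-linked mutation burden and signature fixtures,
so every stage is validated against ground truth. See the methods vignette
(`vignettes/m6Apatterns-methods.Rmd`) for models, parameters and design
rationale.

## Worked example

```r
library(m6Apatterns)

cfg <- pipeline_config(preset = "planted", seed = 7, outdir = "demo_run")
run_pipeline(cfg)
summarize_run("demo_run")
```

which prints (computed output, seed 7):

```
m6Apatterns run digest (demo_run)
  cohort: 150 samples x 2000 genes (preset planted, seed 7)
  m6Acluster consensus: selected_k = 3, sizes A=89, B=25, C=36
  DEG screen: 483 genes at p < 0.0001; prognostic panel: 53 genes at p < 0.001
  gene-cluster consensus: selected_k = 3
  m6Ascore: HR 1.159 (univariate), 1.157 (multivariate); log-rank p = 7.01e-10
  AUC: year_1=0.761, year_2=0.731, year_3=0.779, year_4=0.847
  TMB-score Spearman rho = -0.783
```

Reading it: consensus clustering recovered the three planted modification
patterns (`selected_k = 3`); the moderated screen found 483
cluster-discriminating genes of which 53 survive the univariate Cox filter;
the m6Ascore built on that panel is a significant hazard factor per unit of
score in both the univariate and the covariate-adjusted Cox model
(HR ≈ 1.16; here the score is risk-oriented — its orientation is
data-driven and recorded, not hard-coded), separates high/low groups at
log-rank p ≈ 7e-10, predicts 1–4-year survival with IPCW AUC 0.73–0.85,
and is negatively correlated with tumor mutation burden as planted
(Spearman rho ≈ −0.78).

Every stage is also exposed individually (`consensus_cluster()`,
`ssgsea_score()`, `estimate_scores()`, `moderated_anova()`, `cox_screen()`,
`compute_m6ascore()`, `dichotomize_score()`, `td_auc()`,
`tmb_integration()`, `regulator_network()`, ...), and as a CLI:

```sh
Rscript inst/cli/m6apipe.R run-all --preset planted --seed 7 --out demo_run
Rscript inst/cli/m6apipe.R summarize --run demo_run
```

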