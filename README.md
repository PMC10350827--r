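# NeoVolNorm

Normative modelling of neonatal regional brain volumes, with individualized
deviation z-scores for atypical cohorts and the full downstream statistical
battery.

## What problem this solves, and for whom

Regional brain volumes in newborns change rapidly with postmenstrual age
(PMA) and differ by sex and degree of prematurity. A small clinical cohort
(e.g. neonates with a genetic syndrome or congenital heart defect) cannot be
compared to controls on raw volumes: each subject must be placed against
what is expected *for that subject's sex and age*. NeoVolNorm is for
researchers who have **tabulated segmentation volumes** (cm³ per segment per
subject, as CSV — no images) and want:

1. a **normative reference model** per volumetric measure, learned on a
   preterm-to-term control cohort with Gaussian-process regression over
   sex, PMA at scan and age from birth;
2. **deviation z-scores** for each subject of an atypical cohort,
   `z = (observed − predicted mean) / predictive SD`, with deviations
   flagged *extreme* at |z| ≥ 2.6 (the top and bottom ~0.5% of the
   reference population);
3. the **statistical battery** used on such z-scores: Mann–Whitney U,
   Kruskal–Wallis, Cliff's delta with effect-size bands,
   Benjamini–Hochberg FDR, Spearman bands, LMS growth-chart z-scores,
   OLS and quantile (median/quartile) regression of z against age, extra
   sum-of-squares F-tests for slope/intercept differences between groups,
   and whole-brain-volume (WBV) covariation analysis with WBV-adjusted
   group median z-scores.

The normative model per measure is a GP with kernel

    k(x,x') = σ_f² exp(−½ Σ_d (x_d − x'_d)²/ℓ_d²) + σ_lin² xᵀx' + σ_n² δ

on standardized covariates, hyperparameters maximizing the marginal
likelihood (L-BFGS, analytic gradients, 5 seeded restarts). The predictive
SD includes σ_n², so control z-scores are approximately standard normal.

A synthetic cohort generator (logistic growth in PMA, multiplicative sex
offset, heteroscedastic noise, seed sub-streams per subject, injectable
per-measure deviations with an emitted truth table) makes the entire
pipeline testable without access to restricted neonatal imaging data.

## Segmentation taxonomy

19 tissue segments (frontal/temporal/parietal/occipital/insula/cingulate
GM and WM, cerebellum, brainstem, caudate, lentiform, thalamus,
hippocampus, amygdala), extra-cerebral CSF (eCSF) and lateral ventricles,
plus an optional unlabelled intracranial remainder. Derived whole-brain
volumes: `TTV` (tissue + unlabelled), `TBV` (TTV + lateral ventricles),
`ICV` (TBV + eCSF). Relative volumes divide tissue measures by TTV,
lateral ventricles by TBV, eCSF by ICV.

Note: whether the hippocampus and amygdala belong inside the deep
grey-matter composite is a taxonomy choice; NeoVolNorm counts them in TTV
but **not** in `total_deep_gm` (which is caudate + lentiform + thalamus +
unlabelled remainder), following the segmentation's membership lists
literally.

## Worked example

```r
library(NeoVolNorm)

spec     <- cohortSpec(n = 493, seed = 2)       # study-scale control cohort
controls <- generateControls(spec)
controls
#> VolumetricExperiment with 493 subjects and 22 segments
#> groups: control=493
#> PMA at scan: 31.82-45.87 weeks (median 41.71)

model <- fitNormative(controls, measure = "cerebellum", seed = 2)
model
#> NormativeModel for measure: cerebellum
#>   n = 493 controls, log marginal likelihood = -340.876
#>   kernel: RBF(s2=8.62, ls=[20.77, 4.39, 2980.96]) + lin(6.14e-06) + noise(0.221)

# held-out controls should be standard normal
held <- generateControls(spec, streamOffset = 500000L)[, 1:400]
cal  <- calibrationReport(model, held,
                          measureMatrix(held, "absolute")["cerebellum", 1:400])
round(c(mean = cal$mean_z, sd = cal$sd_z, ks = cal$ks_stat), 3)
#>  mean    sd    ks
#> 0.072 0.990 0.062

# an atypical cohort with a known injected cerebellar deficit of -1.8 SD
at <- generateAtypical(spec, deviationSpec("cerebellum", -1.8),
                       list(cerebellum = model), n = 25)
sc <- zscore(model, at$cohort)
median(sc$z)
#> [1] -1.720131
```

The calibration summary says the model places unseen controls at mean z ≈ 0
with unit spread (well-calibrated normative bands); the atypical group's
median z recovers the injected −1.8 SD deficit to within sampling error of
a 25-subject cohort.

The full pipeline — model battery, group comparison with FDR and Cliff's
delta, age regressions with quantile fits and slope F-tests, CHD-style
subgroup contrasts, and WBV covariation — is one call:

```r
res <- runNormativePipeline(controls, at$cohort, outDir = "reports",
                            seed = 2, subgroupVar = "chd")
res$comparison[res$comparison$measure == "cerebellum",
               c("median_atypical", "p_fdr", "cliffs_delta", "effect_category")]
```

writing `comparison_absolute.csv`, `age_regression.csv`,
`age_slope_comparison.csv`, `covariation.csv`, per-cohort z-score tables
and a JSON run manifest into `reports/`. A thin command-line wrapper lives
in `inst/scripts/run_pipeline.R` (YAML config; see
`defaultAnalysisConfig()`).

### Input CSV schemas

* **volumes**: `subject_id` + one column per segment
  (`requiredSegmentNames()`; `unlabeled_intracranial` optional), cm³.
* **demographics**: `subject_id`, `sex` (`female`/`male`), `ga_birth`,
  `pma_scan` (weeks, decimal), `group`, optional `chd`, `singleton`,
  weight/head-circumference columns.

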