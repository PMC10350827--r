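---
title: "Normative modelling of neonatal regional brain volumes"
author: "NeoVolNorm authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modelling of neonatal regional brain volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Regional brain volumes in the neonatal period change faster than at any
other point in postnatal life, and they differ systematically by sex and by
the degree of prematurity. Comparing a small clinical cohort (for instance
neonates with a genetic syndrome) against typically developing newborns
therefore cannot rely on raw group means: every subject must first be
placed against what is *expected for that subject's sex and age*. NeoVolNorm
implements this normative-modelling strategy for tabulated segmentation
volumes: a reference model is learned on a large preterm-to-term control
cohort, and each subject of interest is expressed as a deviation z-score in
units of the model's predictive SD. The downstream battery (rank tests,
dominance effect sizes, FDR, age and whole-brain-covariation regressions)
then operates entirely on those z-scores.

## Data model

The cohort container is a `SummarizedExperiment` subclass
(`VolumetricExperiment`): one `volumes` assay of absolute segment volumes in
cm³ (19 tissue segments, extra-cerebral CSF, lateral ventricles, and an
optional unlabelled intracranial remainder defaulting to zero), with the
subject covariates in `colData`. Three whole-brain denominators are derived
by exact summation:

* **TTV** — the 19 tissue segments plus the unlabelled remainder;
* **TBV** — TTV plus the lateral ventricles;
* **ICV** — TBV plus the extra-cerebral CSF.

Relative volumes divide tissue segments and tissue composites by TTV, the
lateral ventricles by TBV and the eCSF by ICV. Two membership conventions
deserve note, because the segmentation taxonomy leaves them open:

* *total deep grey matter* comprises caudate, lentiform, thalamus and the
  unlabelled intracranial remainder — hippocampus and amygdala are counted
  in TTV but not in the deep-GM composite, following the taxonomy's
  membership list literally;
* the *unlabelled intracranial remainder* models the segmentation's
  "intracranial background" label without requiring such an artifact to be
  present; it defaults to zero.

Left/right hemispheres are not distinguished (bilateral totals only), and
the package never touches images: it consumes and produces delimited text.

## The normative model

For each measure (absolute or relative, one independent model per measure)
the control cohort is modelled with Gaussian-process regression over three
covariates: sex (female = 0, male = 1), postmenstrual age at scan (weeks)
and age from birth (weeks). All covariates and the target are standardized
internally. The kernel is

\[
k(x, x') \;=\; \sigma_f^2 \exp\!\Big(-\tfrac12 \sum_{d=1}^{3}
  \frac{(x_d - x'_d)^2}{\ell_d^2}\Big)
  \;+\; \sigma_{lin}^2\, x^\top x' \;+\; \sigma_n^2\,\delta_{x x'},
\]

an anisotropic RBF for smooth local structure, a linear component for the
dominant monotone growth trend, and independent Gaussian noise. This
composition is the conventional choice for monotone growth with local
nonlinearity; nothing in the pipeline depends on the curve being logistic,
polynomial, or otherwise parametric. Hyperparameters maximize the log
marginal likelihood by L-BFGS with analytic gradients, restarted from five
seeded log-uniform draws (first start at unit values; best likelihood wins,
ties broken by first found), so a fit is bit-reproducible given the same
data and seed. A jitter of 1e-8 is added to kernel diagonals for Cholesky
stability.

Two modelling decisions matter for interpretation:

* **The predictive SD includes the noise variance.** The z-score divides by
  \(\sqrt{\operatorname{var}_{post}(f_*) + \sigma_n^2}\). Without the noise
  term, control z-scores would have SD well above 1 and the extreme-deviation
  threshold would lose its reference-population meaning.
* **Out-of-range prediction warns but does not fail.** Clinical cohorts can
  extend slightly past the control age range; predictions more than two
  weeks outside the training range are flagged in a warning and still
  returned.

A deviation z-score is \((\text{observed} - \text{predicted mean}) /
\text{predictive SD}\), and a deviation is *extreme* when
\(z \le -2.6\) or \(z \ge +2.6\) (inclusive). Each standard-normal tail
beyond 2.6 holds about 0.47% — the top and bottom half-percent of the
reference population.

```{r}
library(NeoVolNorm)
spec <- cohortSpec(n = 493, seed = 1)
controls <- generateControls(spec)
model <- fitNormative(controls, measure = "cerebellum", seed = 1)
held <- generateControls(spec, streamOffset = 500000L)[, 1:400]
calibrationReport(model, held,
                  measureMatrix(held, "absolute")["cerebellum", 1:400])
```

## The statistical battery

* **Group comparison** — Mann–Whitney U per measure (exact permutation
  distribution when \(nm \le 64\) with no ties, otherwise the
  tie-corrected, continuity-corrected normal approximation), Cliff's delta
  \(d = [\#(x_i > y_j) - \#(x_i < y_j)]/(nm)\) with magnitude bands
  negligible/small/medium/large at cut-points 0.148, 0.34 and 0.475 (the
  banding convention prints gaps, e.g. between 0.33 and 0.34; values in a
  gap resolve to the lower band), and Benjamini–Hochberg adjustment within
  each report table — one FDR family per analysis table, the most common
  reporting convention; the family is simply the set of measures passed to
  one call.
* **Kruskal–Wallis** for more than two groups (tie-corrected H,
  chi-square reference).
* **Spearman correlation** with strength bands; the printed band edges
  (0.19/0.20, 0.39/0.40, ...) are implemented as midpoint cut-points
  0.195, 0.395, 0.595, 0.795 so the mapping is total.
* **LMS growth-chart z-scores** for weight and head circumference:
  \(z = ((x/M)^L - 1)/(LS)\), with the log-limit \(z = \ln(x/M)/S\) for
  \(|L| < 10^{-7}\); L, M and S are interpolated linearly in age within
  sex and ages outside the reference grid are an error, never an
  extrapolation. A small synthetic reference table ships in
  `inst/extdata/lms_reference_synthetic.csv` purely as a format example —
  real analyses must supply a published reference.

## Regression analyses

Age regressions fit each measure's z-scores against PMA at scan with OLS
(slope, intercept, R², adjusted R², overall F) and with quantile
regression at \(\tau = 0.25, 0.5, 0.75\). The quantile fit minimizes the
check loss \(\sum_i \rho_\tau(y_i - a - b x_i)\); because an optimal line
interpolates two data points, the solver combines iteratively reweighted
least squares on an \(\varepsilon\)-smoothed loss with an exact search over
lines through low-residual point pairs (all pairs when \(n \le 60\)), and
is validated in the tests against a dense grid-search oracle. The median
fit's AIC uses the asymmetric-Laplace working likelihood,
\(\mathrm{AIC} = 2k + 2n\ln(\text{mean check loss})\) with \(k = 2\); only
differences between fits to the same data are meaningful, and a zero-loss
fit is reported as \(-\infty\).

Slope differences between groups use the extra sum-of-squares F-test in a
hierarchical convention: first separate-lines vs shared-slope (the slope
test), then — conditional on a shared slope — shared-slope vs one pooled
line (the intercept, or elevation, test). Nonlinear age models are not
offered; within the modelled window a linear description of z-against-age
is the intended readout, and the normative model itself already absorbs
nonlinear growth.

The whole-brain covariation analysis asks whether a segment deviates
*beyond* what its whole-brain volume explains. Each segment's z is paired
with the whole-brain z matching its relative-volume denominator (tissue
segments with TTV, lateral ventricles with TBV, eCSF with ICV), a median
regression of segment z on whole-brain z is fitted per group, and the
fitted value at whole-brain z = 0 is the *WBV-adjusted median z* — the
group's typical deviation at control-typical brain size. The two-group
difference of adjusted medians is tested with a seeded subject-level
bootstrap (2000 resamples by default; the resampled refits use the IRLS
fitter without the exact polish, whose error is far below the bootstrap's
Monte-Carlo noise), followed by FDR.

An optional outlier rule excludes points with \(|z| > 5\) from age
regressions with a logged note; it is off by default.

## The synthetic cohort generator

The generator exists so that every downstream stage is testable without
access to restricted neonatal imaging data. It emulates:

* a preterm-to-term control cohort (default n = 500, 17.5% preterm, 49.3%
  female, 11.2% non-singleton, scans between 31 and 46 weeks PMA; preterm
  subjects are scanned either soon after birth or near term-equivalent
  age);
* per-segment logistic growth in PMA with asymptotes giving term-age
  magnitudes of realistic order (TTV of a few hundred cm³, cerebellum
  ~25 cm³), a multiplicative sex offset (6% male–female), and
  heteroscedastic Gaussian noise with SD proportional to the mean (CV 8%),
  so absolute-volume spread fans out with age;
* an atypical cohort drawn from the same process, with configurable
  per-measure deviations injected in predictive-SD units — a constant
  shift and/or an age-interaction slope centred at 40 weeks (emulating a
  gradual deviation from the control mean with advancing age, as seen with
  congenital heart defects), with the injected truth emitted alongside.

Each subject draws from its own seed sub-stream, so enlarging a cohort
never reshuffles existing subjects, and two cohorts from one spec are
independent.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: segmentation errors and motion artifacts,
twin-pair correlation, comorbidity co-occurrence, non-random scan-age
selection, left–right asymmetries, and any non-logistic fine structure of
real growth. Calibration results on synthetic cohorts demonstrate the
statistical machinery, not the biology.

## Numerical choices and degenerate inputs

* GP optimisation bounds log-hyperparameters to \([-12, 8]\); measures with
  exactly zero variance refuse to fit (a constant measure carries no
  normative information), as do cohorts below 30 controls.
* Zero whole-brain denominators raise an explicit degenerate-input error
  rather than propagating NaN.
* Mann–Whitney on a constant pooled sample returns p = 1 with a warning;
  Spearman on constant input errors (rho undefined).
* The exact/approximate Mann–Whitney switch sits at \(nm \le 64\) without
  ties — exact where enumeration is cheap (the clinical-cohort sizes of
  interest), approximate at reference-cohort scale.
* Percentages in demographic summaries are reported to one decimal place,
  volumes to three decimals (cm³) in CSV reports.

## Problem sizes

The packaged analyses run at the scale the methods target: normative fits
on ~500 controls, deviation cohorts of 25, held-out calibration on 400,
type-I-error simulations at 1000–2000 replicates, and a 21-measure
(19 tissue segments + eCSF + lateral ventricles) segment battery for the
full pipeline. On a single CPU the full pipeline on the demonstration
configuration completes in well under ten minutes.

## Known limitations

* One homoscedastic noise variance per model: the generator's (and real
  data's) age-growing noise is absorbed only partially, so held-out
  z-scores are mildly over-dispersed at the oldest ages and compressed at
  the youngest; calibration summaries stay within conventional bands but
  tail counts are not exact.
* No warped or heteroscedastic-likelihood GPs, no centile curves beyond
  mean ± k·SD bands, no longitudinal modelling (single scan per subject).
* The WBV-adjusted median and its bootstrap test are a pragmatic
  definition (median regression evaluated at whole-brain z = 0); other
  covariate-adjustment conventions exist.
* FDR family boundaries default to one family per report table and are
  configurable; there is no cross-table correction.
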