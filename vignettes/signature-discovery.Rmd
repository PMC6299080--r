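---
title: "Stability-bagged LASSO-Cox signature discovery: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-bagged LASSO-Cox signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmipsig)
```

## The procedure

`rmipsig` builds a sparse prognostic expression signature for censored
progression-free survival (PFS) in five stages.

**1. Paired differential-expression screen.** For paired tumour/normal
expression on a log2 scale, each feature's tumour-minus-normal differences
are tested with an empirical-Bayes moderated t. Writing $s^2_g$ for the
per-feature sample variance with $d$ degrees of freedom, the posterior
variance is

$$\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d},$$

and the moderated statistic uses $\tilde s_g$ with $d_0 + d$ degrees of
freedom. The hyperparameters $(d_0, s_0^2)$ are estimated by the method of
moments on $\log s^2_g$: under the scaled-F marginal of the hierarchical
model, the mean and variance of $\log s^2_g$ identify $s_0^2$ through the
digamma and $d_0$ through the trigamma function (inverted by Newton
iteration). Features are called at Benjamini–Hochberg FDR < 0.05 by default
(a raw p < 0.05 switch exists, `de_use_fdr = FALSE`): the FDR rule is the
stricter of the two conventions in circulation for candidate selection, so
it is the default. Zero-variance features get p = 1, a flag, and are
excluded from the hyperparameter fit — shrinkage could resurrect them, but
a feature with literally identical values in every pair carries no testable
signal at this stage.

**2. Scale normalization.** Cohort expression measured as qRT-PCR relative
values $x = 2^{-\Delta C_t}$ is mapped to $\log_2(10^4 x)$, i.e.
$\log_2 10^4 - \Delta C_t$, putting the values on a readable log2 scale.
Input already on a log2 scale (microarray) skips this step
(`expression_scale = "log2"`).

**3. Univariate Cox screen.** One single-covariate Cox model per DE
candidate against the training cohort's PFS; features with Wald p < 0.1
survive. The screen runs on the training cohort: the paired tissue arm has
no survival follow-up in the synthetic setting, and the training cohort is
where the selection ultimately has to work.

**4. Bagged LASSO-Cox selection.** The core of the package. For bootstrap
resample $b = 1, \dots, B$ (subjects drawn with replacement, duplicates
entering the partial likelihood as separate rows — the simplest semantics
for a resampled "training matrix"):

* fit the L1-penalized Cox path
  $\hat\beta(\lambda) = \arg\min_\beta\; -\tfrac1n \ell(\beta) + \lambda \lVert \beta \rVert_1$
  over a 100-point log-spaced grid from $\lambda_{\max}$ (the smallest
  penalty with $\hat\beta = 0$, equal to $\max_j |U_j(0)|/n$) down to
  $0.01\,\lambda_{\max}$, on internally standardized features;
* select $\lambda_{1SE}$ by 10-fold cross-validation with the
  Verweij–Van Houwelingen deviance
  $\mathrm{dev}_k(\lambda) = -2\{\ell_{full}(\hat\beta_{-k}) - \ell_{-k}(\hat\beta_{-k})\}$
  and the one-standard-error rule (each resample gets a fresh seeded fold
  deal, so different resamples legitimately pick different $\lambda$);
* record the nonzero set at $\lambda_{1SE}$.

$\mathrm{RMIP}_j$ is the fraction of resamples in which feature $j$ was
selected. The top-$k$ features by RMIP (default $k = 2$; ties broken
lexicographically by feature id and logged; the largest consecutive RMIP
drop is also reported as an elbow suggestion) form the signature.

**5. Signature, cutoff, evaluation.** An ordinary Cox refit on the selected
features gives the coefficients of the linear risk score; the exact median
of training-cohort scores is the cutoff. Patients with score strictly above
the cutoff are high-risk; a patient attaining the cutoff is low-risk (the
median-attaining patient conventionally sits in the at-or-below group; the
rule is documented and a single place in the code). Validation cohorts are
always classified with the **training** cutoff. Evaluation comprises
Kaplan–Meier curves per risk group (medians with log(−log) Greenwood CIs),
the log-rank test, the response-by-risk contingency table with per-group
progressive rates (percentage of PD, displayed to 2 decimals, exact
fractions retained), Pearson chi-square (or Fisher's exact test for 2×2
tables with an expected cell below 5), a risk-by-progression interaction
Cox model, and IPCW time-dependent AUC.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `B_resamples` | 1000 | resamples | standard bagging depth; recovery experiments use 200 to keep runtimes interactive |
| `cv_folds` | 10 | folds | the conventional CV depth for n in the tens |
| `lambda_path_length` | 100 | grid points | de-facto standard path resolution |
| `lambda_min_ratio` | 0.01 | fraction of λmax | the usual floor when p < n |
| `de_alpha` | 0.05 | FDR level | candidate screen threshold |
| `cox_screen_alpha` | 0.1 | Wald p | deliberately permissive pre-filter |
| `top_k` | 2 | features | two-feature signatures are the use case; the elbow report supports other choices |
| `ties_method` | breslow | — | simpler likelihood, matches microarray-era practice; Efron available |

## Numerical conventions

* **Cox fitting**: full Newton with analytic gradient/Hessian,
  step-halving on likelihood decrease, convergence at max score < 1e-8 or
  likelihood gain < 1e-10, 50-iteration cap. Hitting the cap or
  $|\hat\beta| > 15$ raises a monotone-likelihood (separation) warning.
  Wald CIs use the fixed 1.96 quantile.
* **Path solver**: IRLS with the diagonal of the partial-likelihood
  Hessian, inner cyclic coordinate descent with soft-thresholding over a
  KKT-screened working set, warm starts, written in C++ (the convention of
  this class of software — the bagging loop solves tens of thousands of
  paths). The outer loop terminates only when the *true*
  Karush–Kuhn–Tucker residual is below tolerance: 1e-7 for user-facing
  paths (the package guarantees 1e-6 and verifies it in R), 1e-5 inside
  the bagging loop where only the active set matters. Saturated fits deep
  in the path (common on bootstrap resamples, where the effective sample
  is smaller and quasi-separation appears) are handled as standard
  survival-lasso software does: in cross-validation/bagging the path is
  truncated at saturation (per-step likelihood gain below 1e-5 of the null
  magnitude, or more than one coefficient per two events, or
  non-convergence); direct path calls instead raise an error naming the
  lambda index. Coefficients below 1e-10 on the standardized scale are
  clipped to exact zero so the active set is well defined at
  $\lambda_{\max}$.
* **1-SE rule**: $\lambda_{1SE}$ is the largest $\lambda$ whose mean fold
  deviance is within one SE (over folds) of the minimum, evaluated over
  the $\lambda$ columns all folds completed.
* **KM medians**: smallest $t$ with $\hat S(t) \le 0.5$; "not reached"
  (`NA`) when the curve stays above 0.5. Median CI limits are the smallest
  times at which the log(−log) Greenwood band reaches 0.5.
* **Determinism**: one master seed expands into per-stage child seeds by a
  fixed counter scheme (`child_seed`), and every sampler
  saves/restores the global RNG state, so identical inputs and
  configuration reproduce byte-identical artifacts.

## The synthetic study

The generator (`simulation_design`, `simulate_paired_tissues`,
`simulate_cohort`, `write_fixture_set`) emulates the data a two-arm
biomarker study produces, with ground truth stored alongside (and read by
no pipeline stage — the test suite verifies this at the artifact level):

* **Paired arm** (default 21 pairs, 200 features): log2 expression with a
  shared within-pair effect; 15% of features shifted by ±1.5 log2-fold in
  tumour. Differences have sd $0.8\sqrt2$, so the default screen has high
  power at 21 pairs — matching a design where the paired arm is the
  generous screen, not the bottleneck.
* **Cohort arm** (default 67 patients): expression directly on the
  $\log_2(10^4\cdot 2^{-\Delta C_t})$ scale with feature means shared
  across cohorts from one design (training and validation cohorts measure
  the same assays); fixture files are written on the raw relative scale so
  the pipeline's normalization step is genuinely exercised. PFS follows a
  Weibull proportional-hazards model
  $S(t\mid x) = \exp\{-(t/b)^a e^{\beta^\top (x - \mu)}\}$ with shape
  $a = 1$ by default (exponential, so closed-form checks apply;
  configurable for proportional-hazards stress tests) and scale $b = 13$
  months (≈ 9-month baseline median PFS, typical of first-line advanced
  colorectal cancer). Censoring is an independent exponential truncated at
  a 60-month administrative horizon, its rate calibrated numerically to a
  25% target. Response categories (CR/PR/SD/PD) come from an ordinal logit
  on the true linear predictor with cutpoints giving ≈ 34% CR+PR / 46% SD
  / 20% PD at baseline risk — the mix reported for cohorts of this kind —
  so higher-risk patients progress more.
* **Planted effects**: the default `planted_beta` is `(-0.26, +0.09)`, the
  magnitude of published two-feature signature weights. These defaults
  define *realistic* conditions, not *favourable* ones: at n = 67 the
  one-standard-error rule — which is deliberately conservative, and which
  an independent implementation (`glmnet::cv.glmnet`) reproduces
  exactly — selects the empty model on most resamples at such effect
  sizes. The recovery experiments therefore plant coefficients scaled to
  detectable size, `(-2.0, +1.2)` on sd-0.8 features (hazard ratios ≈ 0.2
  and 2.6 per sd), fixed by pilot Monte Carlo before the tests were
  frozen. The recovery suite documents the pipeline's sensitivity under
  those conditions — planted pair in the top-2 RMIP ranks in ≥ 90% of
  meta-replicates at B = 200, Kaplan–Meier separation in all three cohorts
  in ≥ 90% of replicates — and is silent about weaker signals.

What the generator does **not** emulate: microarray probe-level noise,
batch effects, stromal contamination, assay detection limits, or
non-proportional hazards (beyond the Weibull shape knob). Passing
recovery tests on this generator therefore demonstrates the pipeline's
correctness and its sensitivity under clean proportional-hazards signals,
not robustness to those artefacts.

## Problem sizes used by the verification suite

The acceptance battery runs at a deliberately scaled-down version of the
study design: 33 candidate features × 67 patients with B = 200 resamples
and 20 meta-replicates for RMIP recovery, 25 replicates of the three-cohort
(67/40/44) Kaplan–Meier separation check, 50 replicates for each null
calibration, and 200 brute-force oracle comparisons for the Cox MLE. These
sizes give the binomial checks reasonable resolution while keeping the
whole suite interactive.

## Known limitations and open choices

* The published pooled progressive-rate denominators (12/82 and 22/69)
  disagree by one patient with the sums of the per-cohort tables (82 vs 83
  low, 69 vs 68 high); the per-cohort numbers are the ones recomputed
  here, and the pooled discrepancy is left as found.
* Published post hoc power values (88.3%/98.4%) are not reproducible
  without the original formula and event counts; the package implements
  the Schoenfeld approximation
  $\Phi(|\ln HR|\sqrt{d\,p(1-p)} - z_{1-\alpha/2})$ as a documented
  assumption.
* Whether the original cross-validated deviance was Verweij–Van
  Houwelingen or the basic fold deviance is not documented anywhere; V&VH
  is the primary implementation here (it is what `cv.glmnet` computes with
  `grouped = TRUE`, the default).
* The time-dependent ROC estimator behind published AUC curves is
  similarly unstated; the IPCW cumulative/dynamic estimator is the
  default, a naive ignore-censoring variant sits behind a flag, and no
  AUC value is treated as a reproduction target.
* No multiple-testing correction is applied across the evaluation tables
  (none is conventional for this table layout); stated here for clarity.
* The 67/40 training/testing split of a 107-patient cohort is offered as a
  seeded utility (`split_cohort`) with no claim of matching any historical
  randomization.
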