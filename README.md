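# rmipsig

Bootstrap-stability LASSO-Cox signature discovery for censored survival
outcomes, with resample model inclusion proportions (RMIP).

## The problem

Expression-based prognostic signatures for cancer cohorts are typically
built in three steps: screen candidate features (paired tumour/normal
differential expression, then a univariate Cox screen against
progression-free survival), select a sparse multivariable model, and
dichotomize a linear risk score for clinical use. The selection step is the
fragile one: with tens of candidates and fewer than a hundred patients, a
single LASSO-Cox fit is unstable under resampling. `rmipsig` implements the
bagged variant of that procedure: the entire cross-validated LASSO-Cox
selection is repeated on `B` bootstrap resamples of the cohort, and each
feature is scored by its **resample model inclusion proportion**

```
RMIP_j = #{ resamples in which beta_j != 0 at lambda_1SE } / B ,
```

a direct estimate of how reliably feature `j` survives selection when the
data are perturbed. The top-`k` features by RMIP (default `k = 2`) are
refit by ordinary Cox regression; the resulting linear predictor

```
risk score_i = sum_j beta_j * x_{j,i}
```

is dichotomized at the exact median of the training-cohort scores, and the
low/high risk groups are evaluated by Kaplan-Meier curves with log-rank
tests, response-category contingency analysis (progressive rate per risk
group), risk-by-response interaction Cox models, and IPCW time-dependent
ROC analysis.

The package is aimed at biostatisticians reproducing or stress-testing this
class of pipeline. All survival machinery is implemented from first
principles and verified against independent oracles in the test suite:

* Cox partial likelihood (Breslow and Efron ties) maximized by
  Newton-Raphson with step-halving; Wald HRs and 95% CIs;
* L1-penalized Cox solved by iteratively reweighted least squares with
  cyclic coordinate-wise soft-thresholding over a log-spaced `lambda` path
  from `lambda_max` (KKT conditions verified to 1e-6 along the path);
* 10-fold cross-validated partial-likelihood deviance
  (Verweij-Van Houwelingen) with the 1-SE rule;
* Kaplan-Meier with Greenwood variance and log(-log) median CIs; K-sample
  log-rank; Schoenfeld post hoc power;
* empirical-Bayes moderated t for the paired screen, with
  Benjamini-Hochberg FDR control;
* qPCR-scale normalization `x -> log2(10000 * x)` for relative 2^-dCt
  input;
* IPCW cumulative/dynamic AUC(t) with bootstrap CIs.

A synthetic-data module generates paired tumour/normal expression and
proportional-hazards survival cohorts with planted ground truth (fold
changes, prognostic coefficients, censoring rate, ordinal-logit response
categories), so every stage has a parameter-recovery test bed.

## Worked example

```r
library(rmipsig)

# a synthetic study: 60 features, ~30% differentially expressed, two
# strongly prognostic features planted among them
des <- simulation_design(n_features = 60, de_fraction = 0.3,
                         planted_beta = c(f001 = -2, f002 = 1.2))
paired <- simulate_paired_tissues(des, seed = 1)
cohort <- simulate_cohort(des, seed = 2)

cfg <- pipeline_config(seed = 1, B_resamples = 100,
                       expression_scale = "log2")
man <- run_pipeline(cfg, paired$expression, paired$pairing,
                    cohort$expression, cohort$clinical)

head(man$rmip[order(man$rmip$rank), ], 3)
#>   feature_id rmip count   B rank
#> 1       f001 0.47    47 100    1
#> 2       f002 0.46    46 100    2
#> 3       f021 0.13    13 100    3

man$signature
#> Risk signature:
#>   f001                 -1.9628
#>   f002                 +1.4047
#>   cutoff (training median): 3.4115

man$evaluation$training$km$low
#> KM curve: n = 34, events = 21, median = 37.60 (95% CI 14.44-57.50)
man$evaluation$training$km$high
#> KM curve: n = 33, events = 33, median = 2.33 (95% CI 0.57-3.61)
man$evaluation$training$logrank
#> Log-rank: chi-square = 40.9343, df = 1, p = 1.574e-10
man$evaluation$training$auc
#> AUC(t = 12) = 0.957 [ipcw] (95% CI 0.900-0.990; 39 cases, 27 controls)
```

The bagging stage ranks the two planted features first and second by RMIP
(0.47 and 0.46, against 0.13 for the best null feature); the refit
signature recovers the planted coefficient signs, and the median split
separates the Kaplan-Meier curves (median PFS 37.6 vs 2.3 months,
log-rank p < 1e-9) with a 12-month AUC of 0.96.

## Documentation

The methods vignette (`vignettes/signature-discovery.Rmd`) describes the
statistical model, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, and the package's
numerical conventions and limitations.
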