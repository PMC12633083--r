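# polyhte

Detecting and characterizing **genetically driven heterogeneous treatment
effects (HTE)** in randomized controlled trials, by modelling treatment
response as a function of many pre-trained polygenic risk scores (PRS).

## The problem

An RCT reports one average treatment effect, but responses differ across
patients. When that heterogeneity is genetic, it is carried by
gene-by-treatment (G×T) interactions spread over thousands of variants —
far too diffuse for one-SNP-at-a-time subgroup scans or a single candidate
risk score at trial sample sizes (hundreds to a few thousand
participants). polyhte implements a causal transfer-learning approach:
compress genome-wide genotypes into a panel of PRS trained on large
external GWAS, then estimate and test conditional average treatment
effects (CATE) on that panel.

## The model

Under a polygenic G×T model with standardized genotypes and standardized
treatment coding `T_std ∈ {√((1−p)/p), −√(p/(1−p))}`,

```
Y_i = Σ_j G_ij β_Gj + T_i_std β_T + Σ_j G_ij T_i_std β_Ij + ε_i
```

the *polygenic efficacy score* `S_i = Σ_j G_ij β_Ij` fully determines the
heterogeneity: `CATE_i = A + C·S_i` with `C = 1/√(p(1−p))`. The package
provides:

* **Individual-level pipeline** (`run_mlearner_i()`): inverse-propensity
  pseudo-outcomes `Y_H = T·Y/e − (1−T)·Y/(1−e)` (an unbiased CATE proxy),
  *sequential cross-fitting* (the model predicting fold k is trained only
  on folds 1..k−1, so every prediction is strictly out-of-sample), a
  best-linear-projection test of `Y_H = α + β·τ̂` (HC3 robust; β = 0 means
  no detectable heterogeneity), quantile subgroup ATEs, and PRS importance
  (|t| of each PRS against τ̂). Learners: ridge (glmnet), RBF-SVR, random
  forest, MLP.
* **Summary-statistic pipeline** (`run_mlearner_s()`): per-trait
  PRS-by-treatment z-tests built from GWIS interaction z-scores weighted
  by GWAS z-scores, aggregated with the **Cauchy combination test**
  `T_K = mean(tan((½ − p_k)π))`, `p = ½ − arctan(T_K)/π`, which keeps its
  size under arbitrary dependence between the scanned PRS.
* **Analytic power scaling laws** (`noncentrality()`,
  `power_two_sided()`, `power_curve()`) for the PES×T interaction test
  under within-trial estimation, single-PRS proxies, and transfer
  learning.
* **Synthetic-data engine** (`simulate_trial()`) reproducing the study
  conditions: unit-variance outcome with 10% baseline-PRS variance, 10%
  G×T variance, 25 correlated estimated PRS, linear and nonlinear PES.
* **Comparison baselines** (`single_prs_interaction()`,
  `within_gwis_pes()`, `prspgx()`, `mlearner_snp()`) and a Monte Carlo
  harness (`run_method_comparison()`).

File formats: whitespace/tab-delimited GWAS/GWIS summary statistics with
a column-alias table, PGS-Catalog-style scoring files, delimited dosage
matrices (optional VCF via vcfR), allele harmonization with sign flips
and palindromic-variant removal, and the QC filters standard in this
field (imputation INFO > 0.9, MAF ≥ 0.05, missingness ≤ 0.01,
HWE p ≥ 1e−6).

## Worked example

Simulate a 1000-person trial with a linear genetic HTE and run the
individual-level pipeline with a ridge learner:

```r
library(polyhte)

cfg    <- sim_config(n_rct = 1000, pes_mode = "linear", seed = 7)
trial  <- simulate_trial(cfg, seed = 7)
report <- run_mlearner_i(trial, learner_spec("penalized_linear"),
                         k_folds = 5, q = 3, seed = 7)
glance(report)
#> # A tibble: 1 × 6
#>   p_combined best_learner         n k_folds n_learners  seed
#>        <dbl> <chr>            <int>   <dbl>      <int> <dbl>
#> 1   0.000753 penalized_linear  1000       5          1     7

report$subgroups
#> # A tibble: 3 × 9
#>     bin     n tau_hat_min tau_hat_max     ate    se  ci_low ci_high      p
#>   <int> <int>       <dbl>       <dbl>   <dbl> <dbl>   <dbl>   <dbl>  <dbl>
#> 1     1   267     -2.40       -0.0825 -0.302  0.130 -0.557  -0.0466 0.0205
#> 2     2   267     -0.0778      0.253  -0.0509 0.114 -0.275   0.173  0.657
#> 3     3   266      0.255       1.89    0.311  0.123  0.0698  0.551  0.0115
```

Reading the output: the best-linear-projection slope is 0.59 with
p ≈ 7.5e−4 — strong evidence that the predicted CATE carries real signal
(a slope of 1 would be perfect calibration, 0 pure noise). The tertile
table shows the recovered gradient: individuals predicted to benefit
least have a *negative* estimated treatment effect (−0.30), those
predicted to benefit most a positive one (+0.31), a spread entirely
invisible in the overall ATE (true treatment main effect 0.02 in this
generator). `report$importance` ranks the 25 PRS by how strongly each
tracks the predicted response.

The analytic power side:

```r
pp <- power_params(n_test = 2500, sigma2_I = 0.03, rho = 0.5, alpha = 0.05)
lam <- noncentrality("transfer_rho", pp)   # 4.33
power_two_sided(lam, 0.05)                 # 0.991
```

With a test sample of 2,500 and G×T explaining 3% of response variance,
an estimated PES correlated 0.5 with the truth already gives 99% power —
while the within-trial estimation strategy stays near the nominal level
over the whole realistic 0–5% range (`power_curve("within_gwis", ...)`).

## Package layout

```
R/                 implementation (data model & IO, causal core, learners,
                   sequential cross-fitting, inference, summary-statistic
                   scan, power laws, simulation engine, baselines, CLI)
tests/testthat/    unit, property and acceptance suites
scripts/           acceptance script
vignettes/         methods vignette (model, assumptions, design choices)
inst/cli/          command-line entry point
```
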