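# depimpute

Dependence-aware weighted KNN imputation of entirely missing paired samples,
with a GLS paired t-test that keeps false-discovery control after imputation.

## The problem

In paired tumor–normal expression studies (the motivating setting is miRNA
profiling in colorectal cancer), tissue is not always available for both
members of a pair: for 10–50% of subjects the *normal* sample can be missing
wholesale — every feature at once — while the tumor sample and an extensive
set of demographic/lifestyle covariates are fully observed. Dropping those
subjects (case deletion) wastes up to half the cohort; imputing their normal
profiles and then running an ordinary paired t-test silently treats the
imputed values as fresh, independent observations.

That last step is the trap this package addresses. A KNN-imputed sample is a
convex combination of *observed* samples, so imputed and observed rows are
statistically dependent. Analyses that ignore this dependence underestimate
the variance of the mean paired difference, inflate t statistics, and push
the realized false discovery rate well past the nominal level. `depimpute`
constructs the covariance that the imputation induces and propagates it
through the differential-expression test.

It is written for biostatisticians and genomics analysts with subjects × 
features matrices and per-subject covariates in delimited text.

## The method

**Imputation.** For each normal-missing subject *i*, the *k* nearest fully
observed subjects are found in covariate space: Euclidean distance on the
standardized continuous covariates, Manhattan distance on the binary ones,
each matrix min–max scaled to [0, 1] and combined as a weighted average.
With sorted neighbor distances D_{i1} ≤ … ≤ D_{ik} and D_{i(max)} the
maximum distance from *i* over all fully observed subjects,

    w_il = 1 − D_il / D_i(max),      a_il = w_il / Σ_t w_it,

and the missing profile is imputed feature-wise as
x̂_ij = Σ_l a_il · x_{i_l j}, or in matrix form **X̂ = AᵀX** with A the
(N−S)×S weight matrix over the S missing subjects.

**Induced covariance.** Ordering subjects observed-first, the joint
covariance of observed and imputed normal samples for any feature j is
σ_j² Σ̃ with the block structure

    Σ̃ = [ I    A  ]
         [ Aᵀ  AᵀA ].

**Testing.** Per feature, the tumor−normal differences D̃_j follow the
one-mean model D̃_j = 1μ_j + ε, Var(ε) = σ_j² V with V = I + Σ̃ (identity
for the dependence-ignoring analysis). Generalized least squares gives

    μ̂_j = (1ᵀV⁻¹1)⁻¹ 1ᵀV⁻¹D̃_j,     σ̂_j² = (D̃_j − 1μ̂_j)ᵀ V⁻¹ (D̃_j − 1μ̂_j) / (N−1),
    Var(μ̂_j) = σ̂_j² (1ᵀV⁻¹1)⁻¹,    t_j = μ̂_j / √Var(μ̂_j)   with N−1 df,

followed by Benjamini–Hochberg adjustment across features. V is
feature-independent, so it is Cholesky-factored once per analysis.

A seeded simulation framework (`sim_config()`, `simulate_dataset()`,
`run_study()`, `sweep_k()`) generates paired matrices with known DE truth,
covariates driven by DE tumor expression, and MCAR whole-row missingness, and
scores TPR/FPR/FDR and imputation RMSE for the dependence-aware test, the
dependence-ignoring test, column-mean imputation, case deletion, and the
full-data reference.

## Worked example

```r
library(depimpute)

cfg <- sim_config(N = 100, G = 500, missing_fraction = 0.3, k = 10, seed = 1)
ds  <- simulate_dataset(cfg)
ds$pes
#> <paired_expression_set> 100 subjects x 500 features; 30 normal sample(s) missing

D   <- covariate_distance(ds$cov)          # mixed-type aggregated distance
nw  <- neighbor_weights(D, ds$pes$missing_mask, k = 10)
imp <- knn_impute(ds$pes, nw)
imp
#> <imputation_result> 30 subject(s) imputed from 70 donors (k = 10)
tidy(nw)
#> # A tibble: 300 × 6
#>   subject neighbor  rank distance weight_raw weight
#> 1 s003    s095         1   0.0789      0.881  0.126
#> 2 s003    s066         2   0.112       0.832  0.119
#> ...

dep <- run_de_analysis(ds$pes, imp, mode = "dependent",   alpha = 0.05)
ind <- run_de_analysis(ds$pes, imp, mode = "independent", alpha = 0.05)
dep
#> <de_result> mode = dependent; 500 features, 23 significant at BH 0.05
ind
#> <de_result> mode = independent; 500 features, 73 significant at BH 0.05

confusion_metrics(tidy(dep)$significant, ds$truth$de_indicator)
#>     tpr    fpr    fdr
#> 1  0.22 0.0025 0.0435
confusion_metrics(tidy(ind)$significant, ds$truth$de_indicator)
#>     tpr    fpr   fdr
#> 1  0.58 0.0375 0.205
```

Both analyses see the same imputed data. The dependence-ignoring test calls
73 features and one in five of its calls is false (FDR 0.205, four times the
nominal 0.05); the dependence-aware test calls fewer features but keeps the
realized FDR at 0.043. At the full study scale (N = 400, 50% missing) the
power cost shrinks to a few percent while the FDR gap widens — see the
vignette and `run_study()`.

`tidy()`, `glance()` and `autoplot()` methods are provided for neighbor
weights, imputation results, DE results, study reports and k-sweeps. A thin
command-line wrapper (`inst/exec/depimpute`, or `depimpute_main()` in R)
exposes `distance`, `impute`, `test`, `simulate` and `study` subcommands over
delimited text files, with YAML configs and JSON run manifests.

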