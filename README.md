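# blocklink

Sparse multiblock canonical correlation pipelines linking a blood
gene-expression block and a brain region-of-interest (ROI) activity block
to a binary clinical phenotype.

## What it is for

Imaging-transcriptomics studies measure two heterogeneous blocks of
variables on the same subjects — say, relative expression of ~33 candidate
genes in peripheral blood and mean BOLD response amplitudes in 16 ROIs —
and ask how they jointly relate to a diagnosis (e.g. schizophrenia vs.
healthy control). Variable-by-variable regressions ignore the correlation
structure and bleed power across dozens of tests. `blocklink` implements
the multiblock alternative: each modality is a block `X_j`, summarized by
one latent component `y_j = X_j a_j`, with the weight vectors estimated by
maximizing the generalized canonical correlation criterion

```
max over a_j:  sum_{j,k} C[j,k] * g( cov(X_j a_j, X_k a_k) )
subject to     a_j' M_j a_j <= 1            (regularized mode)
        or     ||a_j||_2 <= 1, ||a_j||_1 <= s_j * sqrt(p_j)   (sparse mode)
```

where the binary design matrix `C` encodes the causal hypothesis
connecting the blocks (`sequential`: RNA–IMG–DX, `complete`: all pairs,
`reversed_sequential`: IMG–RNA–DX), `g` is a scheme function (identity,
square, or absolute value), and the sparse constraints select a small,
interpretable signature per block. Around this core the package provides
the full analysis chain:

* `fit_residualizer()` / `preprocess_dataset()` — OLS residualization on
  age, sex, smoking, then standardization; training-fold models are reused
  on test folds so cross-validation never leaks;
* `fit_group_models()`, `adjust_bh()`, `mancova()` — the univariate
  screen with Benjamini–Hochberg adjustment at an explicit family size,
  and the per-block multivariate baseline;
* `sgcca_fit()`, `build_design()`, `project_l1_l2()` — the block-relaxation
  fitter with monotone criterion trace;
* `cross_validate()`, `stability_summary()`, `compare_designs()` —
  externally cross-validated LDA on the latent components, inner-CV
  sparsity tuning, per-variable occurrence counts and mean absolute fold
  loadings ("Meanf"), and design comparison by error-rate distributions;
* `assign_reference()`, `relative_quantity()` — 2^-ddCt relative
  quantification of Ct-level qPCR data with expression-intensity reference
  windows, producing the expression block;
* `synthetic_spec()` / `generate_multiblock()` — a seed-deterministic
  generator of two-block + phenotype datasets with a planted latent causal
  chain, used throughout the tests;
* `read_dataset()`, `run_pipeline()` — TSV I/O and a one-call pipeline
  writing all artifact tables plus a reproducibility manifest.

## Worked example

```r
library(blocklink)

spec <- synthetic_spec(n_case = 30, n_control = 30,
                       beta_dx_img = 1.5, beta_img_rna = 1.5,
                       causal_variant = "sequential", seed = 42)
ds <- generate_multiblock(spec)
ds
#> Multiblock dataset: 60 subjects, 30 patients / 30 controls
#>   block 'RNA': 33 variables
#>   block 'IMG': 16 variables
#>   covariates: age, sex, smoking

head(fit_group_models(ds), 5)
#>   variable block coef    raw_p    adj_p
#> 1     roi3   IMG 2.84 4.42e-12 2.16e-10
#> 2     roi1   IMG 2.37 3.47e-10 8.50e-09
#> 3    gene1   RNA 2.34 8.20e-10 1.34e-08
#> 4     roi4   IMG 2.32 3.41e-09 4.18e-08
#> 5     roi2   IMG 2.40 6.99e-09 6.60e-08

mancova(ds$blocks$IMG, ds$phenotype, ds$covariates)
#>      term df statistic approx_f num_df den_df  p_value
#> 1   group  1     0.825   11.789     16     40 1.79e-10
#> 2     age  1     0.209    0.660     16     40 8.14e-01
#> 3     sex  1     0.282    0.984     16     40 4.91e-01
#> 4 smoking  1     0.318    1.165     16     40 3.35e-01

cv <- cross_validate(ds, build_design("sequential"), seed = 1)
mean(cv$error_rates)
#> [1] 0.1333333
head(cv$signature$IMG[, 1:4], 5)
#>   variable meanf occurrence robust
#> 1     roi2 0.556          5   TRUE
#> 2     roi3 0.417          4   TRUE
#> 3     roi4 0.394          4   TRUE
#> 4     roi1 0.378          4   TRUE
#> 5     roi8 0.077          2  FALSE
```

The screen picks out the planted signal columns (`roi1`–`roi4`,
`gene1`–`gene5`); the MANCOVA shows a strong group effect on the imaging
block and none for the covariates; the 5-fold cross-validated LDA on the
two latent components misclassifies ~13% of held-out subjects; and the
stability table flags exactly the planted ROIs as robust (selected in at
least 3 of 5 folds, here 4–5), with `meanf` the mean absolute loading
across folds. BH adjustment at an explicit family size reproduces
published screening arithmetic:

```r
signif(adjust_bh(c(7.28e-5, 2.02e-4, 8.29e-4), m = 52), 3)
#> [1] 0.00379 0.00525 0.01440
```

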