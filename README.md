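# pmkl — shrinkage estimation for Poisson regression under multicollinearity

`pmkl` is an R package for fitting count-data regression models whose
predictors are strongly correlated. In the Poisson regression model
(counts `y_i ~ Po(mu_i)` with `mu_i = exp(x_i' beta)`), near-collinear
predictors make the smallest eigenvalues of the weighted cross-product
`X'LX` (with `L = diag(mu_i)`) approach zero, and the maximum likelihood
estimator — whose scalar mean squared error is `sum_j 1/lambda_j` —
becomes wildly unstable. The package implements the family of shrinkage
estimators that address this, together with the theory needed to compare
them:

* **IWLS fitting** of the Poisson MLE with exposed weights, working
  response and spectral (canonical) decomposition;
* the **Poisson ridge** (PRE), **Poisson Liu** (PLE), **Poisson
  Kibria–Lukman** (PKL) and **Poisson modified Kibria–Lukman** (PMKL)
  estimators — the last applies the KL filter to the ridge estimator,
  giving the canonical shrinkage factor
  `lambda (lambda - k) / (lambda + k)^2` that damps unstable directions
  hardest;
* every **data-driven biasing-parameter rule** for the family (ridge k,
  Liu d-hat, KL k, and the k1/k2/k3 rules for the modified KL, the last
  solving the per-component MSE stationarity condition);
* closed-form **theoretical MSE** expressions and numerical
  **matrix-MSE dominance checks** between any two estimators;
* a **Monte-Carlo experiment engine** comparing all estimators over grids
  of sample size, collinearity level and intercept, with per-cell
  standard errors and convergence bookkeeping;
* **collinearity and goodness-of-fit diagnostics** and CSV dataset I/O,
  plus a command-line front end (`inst/cli/pmkl.R`).

It is aimed at statisticians and epidemiologists modelling counts with
correlated covariates, and at researchers studying shrinkage estimators
themselves.

## Worked example

Generate a small, strongly collinear count dataset, check the diagnostics,
and compare all estimators:

```r
library(pmkl)

f <- tempfile(fileext = ".csv")
generate_fixture(n = 40, p = 3, rho = 0.99, intercept = 1, seed = 42, path = f)
s <- load_dataset(f, response = "y")

collinearity_diagnostics(s)
#> Collinearity diagnostics (predictor block X'X)
#>   eigenvalues: 90.9795, 0.992297, 0.498128
#>   condition number (sqrt convention): 13.5145
#>   eigenvalue ratio: 182.6426
#>   multicollinearity flag (threshold 30): TRUE

res <- fit_all_estimators(s)
print(res$table, digits = 3)
#>   estimator (Intercept)       x1    x2    x3 param          rule scalar_mse
#> 1       MLE       0.802 -0.12723 1.245 0.746    NA                    0.878
#> 2       PRE       0.806 -0.01479 1.155 0.724 0.556 ridge_default      0.594
#> 3       PLE       0.808  0.05264 1.101 0.712 0.000   liu_default      0.489
#> 4       PKL       0.807 -0.00538 1.148 0.722 0.278   pkl_default      0.567
#> 5     PMKL1       0.811  0.17523 1.002 0.689 0.556            k1      0.381
#> 6     PMKL2       0.812  0.20182 0.981 0.684 0.624            k2      0.378
#> 7     PMKL3       0.807 -0.00668 1.149 0.723 0.185            k3      0.571
```

The dataset was generated with true coefficients `(1, 0.577, 0.577,
0.577)`. The eigenvalue ratio of 183 flags strong collinearity, and the
MLE shows the classic symptom: a wrong-signed `x1` and an inflated `x2`.
Each row reports an estimator's coefficients, its selected biasing
parameter and rule, and its estimated theoretical scalar MSE: every
shrinkage estimator improves on the MLE's 0.878, with the modified KL
variants (PMKL1/PMKL2) smallest at ~0.38 — they pull the coefficients
furthest back toward the stable configuration.

Dominance of one estimator over another in the matrix-MSE sense can be
checked directly:

```r
cf <- res$canon
msem_difference(c("MLE", "PMKL"), cf, k = select_k(cf, "mkl_k1"))
#> MSEM comparison: MLE (reference) vs PMKL (challenger)
#>   k = 0.5564
#>   difference eigenvalues: 0.4324, 0.06335, 0.001163, -3.154e-05
#>   challenger dominates: FALSE
```

Here the variance reduction is large along three directions but the
plug-in `k` buys it with slightly too much bias along the fourth — the
two-step criterion (variance-difference positivity plus the scalar bias
condition) reports that honestly instead of declaring a winner.

The Monte-Carlo engine reproduces the standard comparison study:

```r
tab <- run_mse_experiment(n = 50, p = 4, rho = c(0.9, 0.99), intercept = 1,
                          replications = 200, seed = 1)
mse_table_wide(tab)
```

gives one row per `(intercept, n, rho)` cell with the empirical MSE of
each estimator (columns MLE, PRE, PLE, PKL, PMKL1, PMKL2, PMKL3); the long
format (`tab`) carries Monte-Carlo standard errors and convergence counts
per cell.

## Command line

A thin CLI over the package lives at `inst/cli/pmkl.R`:

```sh
Rscript inst/cli/pmkl.R fixture  --n 40 --p 3 --rho 0.99 --seed 42 --out data.csv
Rscript inst/cli/pmkl.R fit      --data data.csv --response y --out fit.csv
Rscript inst/cli/pmkl.R diagnose --data data.csv --response y
Rscript inst/cli/pmkl.R simulate --config sim.yaml --out mse.csv --wide
```

All outputs are CSV; `--verbose` logs seeds and selected parameters to
stderr. See `vignettes/pmkl-methods.Rmd` for the full account of the
model, the selection rules, the simulation design and its limitations.
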