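# lqreg

Sparse linear regression when the errors are heavy-tailed, via the
**Lq-likelihood**: a power-function generalization of the log-likelihood in
which `log` is replaced by the q-logarithm

```
log_q(u) = (u^(1-q) - 1) / (1 - q),   log_1(u) = log(u).
```

The error model is the **q-normal** (Tsallis q-Gaussian) family with density

```
f_q(y | xi, sigma) = (1 / (sigma * Z_q)) * exp_q( -((y - xi)/sigma)^2 / (3 - q) ),
```

which for `1 <= q < 3` interpolates between the normal distribution
(`q = 1`), Student-t with `nu = (3 - q)/(q - 1)` degrees of freedom
(`1 < q < 3`), and the Cauchy distribution (`q = 2`). For the q-normal
linear model `y = X theta + eps` with unit dispersion, the Lq-likelihood is
an affine, decreasing function of the residual sum of squares:

```
Lq(theta | y) = -(Z_q^(q-1) / (3 - q)) * ||y - X theta||^2 + const.
```

Two consequences drive everything in this package:

* the **maximum Lq-likelihood estimator (MLqE) is ordinary least squares**,
  for every q; and
* **Lq-likelihood-based regularization** — minimizing
  `-(1/n) Lq(theta | y) + rho_lambda(theta)` with a LASSO, SCAD, or MCP
  penalty — is a penalized least-squares problem: the LASSO problem at
  `lambda` equals the classical one at
  `lambda' = lambda * (3 - q) / (2 * Z_q^(q-1))` (see `map_lambda()`).

So the ordinary sparse-regression machinery applies unchanged to
heavy-tailed data, and the interesting question — which the simulation
harness measures — is how well model selection and generalization survive
as the tails get heavier. Intended users are statisticians and
biostatisticians fitting sparse linear models where Cauchy-like or
t-distributed noise is a concern.

## What's inside

* `q_spec()`, `log_q()`, `exp_q()`, `nu_of_q()`, `dqnormal()`, `rqnormal()`
  — the q-deformed calculus and the q-normal distribution toolkit.
* `lq_data()`, `lq_likelihood()`, `log_likelihood()`, `mlqe()`,
  `submodel_mle()` — the q-normal linear model: standardized design
  (columns centered, unit Euclidean norm), Lq- and log-likelihoods
  (Student-t errors for q > 1), OLS, and submodel t-regression MLE refits
  by iteratively reweighted least squares.
* `penalty_spec()`, `penalty_value()`, `threshold()` — LASSO, SCAD
  (`a = 3.7`), MCP (`gamma = 3`) penalties and their exact scalar
  thresholding operators.
* `lq_fit()`, `lq_path()`, `lambda_grid()`, `lq_loss_scale()`,
  `map_lambda()` — warm-started cyclic coordinate descent over a
  log-spaced lambda grid, for the least-squares or the Lq objective.
* `aic()`, `bic()`, `lq_aic()`, `lq_bic()`, `evaluate_path()`,
  `select_model()`, `cv_lq()` — model selection along the path: each
  criterion in the MLE-refit ("1") and path-estimate ("2") variants, plus
  K-fold cross-validation.
* `gen_design()`, `gen_true_theta()`, `gen_response()`,
  `experiment_config()`, `run_trial()`, `run_experiment()`,
  `enumerate_cases()` — the synthetic-data generator and Monte Carlo
  harness for exact support recovery and out-of-sample prediction error.
* broom-style `tidy()` / `glance()` and ggplot2 `autoplot()` methods for
  fits, paths, CV curves, and experiment summaries; a thin CLI in
  `exec/lqreg` (`fit`, `path`, `select`, `simulate`).

## Worked example

Simulate a slightly heavy-tailed regression (`q = 3/2`, i.e. t with 3
degrees of freedom), fit an MCP path, and select a model by BIC evaluated
at the path estimates (BIC2):

```r
library(lqreg)
set.seed(42)
X <- gen_design(n = 100, d = 10)
theta <- gen_true_theta(d = 10, rnz = 0.2, theta_star = 10) # slopes 10, 10, 0, ...
y <- gen_response(X, theta, q = 3/2)

path <- lq_path(X, y, penalty = "mcp", q = 3/2)
sel <- select_model(evaluate_path(path, criteria = "BIC2"), "BIC2", path)
dplyr::filter(tidy(path), index == sel$index, estimate != 0)
#> # A tibble: 4 × 4
#>   index lambda term         estimate
#>   <int>  <dbl> <chr>           <dbl>
#> 1    20  0.304 (Intercept)  0.000559
#> 2    20  0.304 x1          11.1
#> 3    20  0.304 x2           9.17
#> 4    20  0.304 x7          -2.61
```

The two true signals (`x1`, `x2`, truth 10) are found with estimates near
the truth; on this draw a small false positive (`x7`) slips in — exact
recovery at this noise level succeeds in a minority-to-half of trials, as
the harness quantifies:

```r
cfg <- experiment_config(q = 3/2, n = 100, d = 10, rnz = 0.2, theta_star = 10,
                         m = 50, criteria = "BIC2", seed = 1)
run_experiment(cfg)$summary[, c("penalty", "criterion", "recovery_count", "median_mse")]
#> # A tibble: 3 × 4
#>   penalty criterion recovery_count median_mse
#>   <chr>   <chr>              <int>      <dbl>
#> 1 lasso   BIC2                  19       2.54
#> 2 mcp     BIC2                  39       2.50
#> 3 scad    BIC2                  33       2.50
```

Out of 50 trials, MCP + BIC2 recovers the exact true support 39 times and
the LASSO only 19 — the nonconvex penalties dominate, and the per-trial
median squared prediction error sits near the t(3) noise variance of 3.
`autoplot(path)`, `autoplot(cv_lq(...))`, and
`autoplot(run_experiment(...))` draw the coefficient paths, CV curve, and
recovery bar charts.

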