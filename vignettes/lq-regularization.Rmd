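---
title: "Lq-likelihood regularization for heavy-tailed linear models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lq-likelihood regularization for heavy-tailed linear models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lqreg)
```

## The model

We consider the linear model
$$ y_a = \theta_0 + \sum_{i=1}^d x_{ia}\theta_i + \varepsilon_a,
   \qquad a = 1, \dots, n, $$
with the standing standardization $\sum_a x_{ia} = 0$ and
$\lVert x_i \rVert = 1$ for every non-intercept column, and i.i.d. errors
from the *q-normal* family with known unit dispersion,
$$ f_q(y \mid \xi) = \frac{1}{Z_q}
   \exp_q\!\Big(-\frac{(y-\xi)^2}{3-q}\Big), \qquad
   \exp_q(u) = \{1 + (1-q)u\}^{1/(1-q)}. $$
For $1 \le q < 3$ this family is supported on the whole real line:
$q = 1$ is the normal distribution, $q = 2$ the Cauchy, and in general
$q = 1 + 2/(\nu+1)$ is Student-t with $\nu = (3-q)/(q-1)$ degrees of
freedom. The normalizing constant is $Z_1 = \sqrt{2\pi}$ and
$Z_q = \sqrt{\nu}\,B(\nu/2, 1/2)$ otherwise; `q_spec()` carries $(q, \nu,
Z_q)$ around, and a unit test confirms the Beta-function form against
adaptive quadrature of the unnormalized kernel. We restrict to
$1 \le q < 3$ at construction: $q < 1$ gives compact support and
$q \ge 3$ a non-normalizable kernel, both outside this package's scope.

One sign convention deserves a note: the q-exponential's domain for
$q > 1$ is the set where $1 + (1-q)u > 0$, i.e. $u < 1/(q-1)$; `exp_q()`
enforces the positivity condition directly rather than any particular
printed inequality.

**Sampling.** `rqnormal()` draws $\xi + \sigma T$ with $T$ standard normal
($q=1$) or Student-t with $\nu$ degrees of freedom ($q>1$). This is the
exact distributional identity, chosen over a generalized Box–Muller-type
transform because it is simple and directly testable against closed-form
normal/t/Cauchy CDFs (the suite checks a Kolmogorov–Smirnov distance
below 0.01 at $n = 10^5$ for the Cauchy case).

## The Lq-likelihood and why the MLqE is OLS

The Lq-likelihood replaces the logarithm in the log-likelihood by the
q-logarithm $\log_q(u) = (u^{1-q}-1)/(1-q)$:
$$ L_q(\theta \mid y) = \sum_{a=1}^n \log_q f_q(y_a \mid x_a\theta). $$
Expanding $\log_q$ of the q-normal density gives
$$ L_q(\theta \mid y) = -\frac{Z_q^{q-1}}{3-q}\,
   \lVert y - X\theta \rVert^2 \; + \; n\,\frac{Z_q^{q-1}-1}{1-q}. $$
`lq_likelihood()` computes the sum directly from the density — the direct
summation is unambiguous, and the affine form above (its slope in
particular) is used as an independent oracle in the tests. Because the
map is affine and decreasing in the residual sum of squares, its
maximizer is the ordinary least-squares solution for *every* q: `mlqe()`
simply solves the normal equations by QR and refuses rank-deficient
designs rather than silently pseudo-inverting. The constant term printed
above differs from a naive $-n\log_q(Z_q)$ by the factor $Z_q^{q-1}$;
since only differences of $L_q$ matter for estimation and the criteria,
the package standardizes on the directly-summed definition throughout.

## Penalties and their scalar thresholding operators

Three penalties are supported, always on the slopes only:
LASSO $\lambda\sum_i|\theta_i|$; SCAD with tuning constant $a > 2$
(default 3.7), stored through its derivative
$\lambda\{1(|\theta|\le\lambda) +
\frac{(a\lambda - |\theta|)_+}{(a-1)\lambda}1(|\theta|>\lambda)\}$ and the
matching antiderivative, whose middle branch
$-(|\theta|^2 - 2a\lambda|\theta| + \lambda^2)/(2(a-1))$ is the unique
reading continuous at both knots (continuity is unit-tested); and MCP
with $\gamma > 1$ (default 3),
$\lambda\int_0^{|\theta|}(1 - u/(\gamma\lambda))_+\,du$. The defaults
$a = 3.7$ and $\gamma = 3$ are the conventional reference values.

`threshold()` returns the exact minimizer of
$\frac{\kappa}{2}(z-\theta)^2 + \rho_\lambda(\theta)$ by enumerating the
stationary point of each polynomial branch (clipped to its branch) plus
the knots, $0$, and $z$; ties resolve to the smaller magnitude, so
degenerate cases deterministically prefer the sparser value. At
$\kappa = 1$ this reproduces soft thresholding and the firm/clipped SCAD
and MCP rules; for $\kappa$ below the penalty's concavity
($\kappa\gamma \le 1$, $\kappa(a-1) \le 1$) the scalar problem is
nonconvex and the enumeration still returns the global minimizer. A
property test draws 1000 random $(z, \lambda, a, \gamma)$ tuples and
compares against brute-force grid minimization at $10^{-5}$ resolution.

## The solver: objective scaling and lambda conventions

The solver minimizes, by cyclic coordinate descent with warm starts along
a decreasing log-spaced $\lambda$ grid,
$$ s \cdot \frac{1}{2n}\lVert y - \tilde X\tilde\theta \rVert^2
   + \rho_\lambda(\tilde\theta), \qquad
   \tilde X = \sqrt{n}\,X, \quad \tilde\theta = \theta/\sqrt{n}, $$
with the intercept unpenalized. The $\sqrt{n}$ rescaling is the standard
convention of coordinate-descent solvers for nonconvex penalties
(columns of squared norm $n$): it makes every coordinate subproblem the
*unit-curvature* scalar problem solved by `threshold()`, so SCAD and MCP
updates are unique and well-behaved, and all three families keep every
slope at zero at
$\lambda_{\max} = \max_i |x_i^\top(y-\bar y)|/\sqrt{n}$, the top of the
default grid (`lambda_grid()`; 100 points, minimum ratio $10^{-3}$ when
$n > d$ and $0.05$ otherwise). Penalizing $\theta$ itself at the
$\lVert x_i\rVert = 1$ scale instead would give each coordinate curvature
$1/n$, making the MCP subproblem nonconvex for any $n > \gamma$ and the
path start dense — a geometry in which nonconvex path-following
degenerates. The two conventions agree for the LASSO up to a relabeling
of $\lambda$; for SCAD/MCP the reference convention is the one under
which the published default tuning constants mean what they usually mean.
Reported coefficients are mapped back to the unit-norm standardized scale
and to the input scale, and `lq_data` keeps the transform record so
destandardized coefficients reproduce fitted values exactly.

Convergence is declared when the largest absolute coefficient change in a
full sweep falls below $10^{-7}$ ($10^4$ sweeps maximum, non-convergence
flagged and the best iterate returned); sweeps are cyclic, not
randomized, so single-threaded runs are bit-reproducible. For the LASSO
the result is the global minimum (KKT conditions are tested); for
SCAD/MCP only coordinate-wise stationarity is guaranteed, with warm
starts providing path continuity.

**The loss scale $s$.** With $s = 1$ (default, `objective = "ls"`) the
solver is classical penalized least squares. With
$s = 2Z_q^{q-1}/(3-q)$ (`objective = "lq"`, see `lq_loss_scale()`) the
loss equals $-(1/n)L_q(\theta\mid y)$ up to a constant, i.e. the
Lq-likelihood-based regularization problem. Because the two losses differ
only by the positive factor $s$, the Lq problem at $\lambda$ has exactly
the minimizers of penalized least squares with penalty
$\rho_\lambda / s$: for the LASSO that is the LASSO at
$\lambda' = \lambda(3-q)/(2Z_q^{q-1})$ (`map_lambda()`), and for the MCP
the MCP at $(\lambda/s,\ \gamma s)$. For SCAD the scaled penalty leaves
the SCAD family, which is why the solver takes the loss-scale route and
solves the Lq objective directly rather than remapping constants. At
$q = 1$, $s = 1$ and everything collapses to the classical problem. This
equivalence — heavy-tailed Lq regularization computable by ordinary
penalized least squares — is the package's central identity and is tested
to $10^{-8}$ on random instances.

## Submodel refits and information criteria

For a path $(\hat\theta^{(k)})$ with supports
$I(k) = \{i: \hat\theta^{(k)}_i \ne 0\}$, `evaluate_path()` computes
AIC $= -2\log p(y\mid\hat\theta) + 2d'$,
BIC $= -2\log p + d'\log n$, and the Lq analogues with $L_q$ in place of
$\log p$, each in two variants: "2" at the path estimate itself, "1" at
the submodel maximum likelihood refit. $d'$ counts the nonzero slopes
plus the intercept — the dispersion is known, so it is not a parameter.
Minimization is over available entries, ties broken toward larger
$\lambda$ (the sparser model), and duplicate supports along the path are
refit once.

The submodel MLE under $q > 1$ is a Student-t regression, computed by
iteratively reweighted least squares with weights
$(\nu+1)/(\nu + r_a^2)$, initialized at the OLS refit, tolerance
$10^{-8}$ on the coefficient change, at most 500 iterations, with
step-halving whenever a reweighted update would decrease the likelihood.
The Cauchy case ($q = 2$) can have a multimodal likelihood, so five
random restarts around the OLS fit are added and the best local maximum
kept. "The MLE exists" is operationalized as: IRLS converged *and* the
analytic Hessian at the solution is negative definite; otherwise the
refit is reported unavailable and the IC1 criteria skip that path point.
This mirrors the caveat that MLE-refit criteria are only defined when the
MLE exists; IC2 criteria are always defined.

`cv_lq()` implements K-fold cross-validation (default $K = 10$ — a
declared default, not something the method dictates) with seeded
contiguous-block folds after a random permutation, a common $\lambda$
grid computed on the full data, and squared-error prediction loss. For
$q \ge 2$ the squared error has no finite mean, so CV under very heavy
tails is intrinsically unstable; the harness documents this rather than
papering over it, which matches the known observation that CV selection
can be occasionally very poor in that regime.

## The simulation harness

`run_experiment()` reproduces, at configurable scale, the Monte Carlo
design over $q \in \{1, 13/11, 3/2, 5/3, 2, 2.01, 2.1, 2.5\}$ (any
$q \in [1,3)$ is accepted), $n \in \{100, 1000\}$, $d \in \{10, 100\}$,
nonzero ratio $r_{nz} \in \{0.2, 0.4, 0.6, 0.8\}$ and nonzero magnitude
$\theta^* \in \{1, 10, 100, 1000\}$ (`enumerate_cases()` lists the full
32-cell factorial). Each trial draws a fresh i.i.d. standard-normal
design, standardizes it, places the $d \cdot r_{nz}$ nonzero slopes (all
equal to $\theta^*$) in the leading coordinates — position is immaterial
by exchangeability of the design, which a permutation test confirms —
and adds unit-dispersion q-normal noise. All configured penalties are
path-fit, all configured criteria select, and exact support recovery is
recorded.

Design choices that were genuinely open:

* **Generalization metric.** Prediction error is measured on one fresh
  test set per trial, of the same size $n$, same design law, same true
  coefficients, fresh q-normal errors; reported per observation as mean
  squared error, with mean absolute error and across-trial medians
  emitted alongside because squared error has infinite variance for
  $q \ge 2$. Building $m$ test copies per trial would multiply cost
  without changing the Monte Carlo mean at this scale; the single-copy
  choice is recorded in the summary's metadata columns.
* **Per-trial seeds** derive from the master seed by a linear counter
  scheme modulo a prime below $2^{31}$, so any trial can be re-run in
  isolation and runs are bit-for-bit reproducible (tested).
* **Default scale** is $m = 100$ trials (configurable up to the
  full-scale $m = 1000$): the package's test suite and examples use desk
  scale, and the qualitative findings (MCP dominating LASSO for
  moderate signals, degradation at $q = 2.5$, monotone improvement in
  $\theta^*$) are already stable there. The acceptance-style checks in
  the suite run at $m = 100$ with $n = 100$–$1000$, $d = 10$.

**What the generator does not emulate.** Real design matrices are
correlated, heteroscedastic, and often contain outliers in $X$ as well as
in $y$; the generator's columns are independent Gaussians, and its errors
are exactly q-normal with known unit dispersion. Passing tests therefore
demonstrate correctness of the machinery and the qualitative tail-index
story under the stated conditions, not robustness of the selected models
to design correlation, dispersion misspecification, or contamination.
Estimation of the dispersion $\sigma$ is deliberately out of scope
($\sigma = 1$ throughout), as is any asymptotic theory of the MLqE.

## Numerical summary of defaults

| Quantity | Default | Where |
|---|---|---|
| SCAD $a$ | 3.7 | `penalty_spec()` |
| MCP $\gamma$ | 3 | `penalty_spec()` |
| Path length | 100 | `lambda_grid()` |
| $\lambda_{\min}/\lambda_{\max}$ | $10^{-3}$ ($n>d$), $0.05$ otherwise | `lambda_grid()` |
| CD tolerance / max sweeps | $10^{-7}$ / $10^4$ | `lq_path()` |
| IRLS tolerance / max iter | $10^{-8}$ / 500 | `submodel_mle()` |
| Cauchy restarts | 5 | `submodel_mle()` |
| CV folds | 10 | `cv_lq()` |
| Trials $m$ | 100 | `experiment_config()` |

```{r example}
set.seed(1)
X <- gen_design(100, 10)
y <- gen_response(X, gen_true_theta(10, 0.2, 10), q = 3/2)
path <- lq_path(X, y, penalty = "mcp", q = 3/2)
sel <- select_model(evaluate_path(path, criteria = "BIC2"), "BIC2", path)
sel$support
```
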