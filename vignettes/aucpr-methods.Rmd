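---
title: "Methods: AUC-maximizing marker combinations by penalized covariance regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AUC-maximizing marker combinations by penalized covariance regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aucpr)
```

## The model

Consider two classes of samples measured on a common panel of $p$ markers:
non-diseased (controls) $X_i \sim N(\mu_x, \Sigma_x)$, $i = 1, \dots, m$, and
diseased (cases) $Y_j \sim N(\mu_y, \Sigma_y)$, $j = 1, \dots, n$.  For a
linear score $\beta' z$ the AUC — the probability that a random case scores
above a random control — is $\Phi\!\big(\beta'\mu / \sqrt{\beta' \Sigma
\beta}\big)$ with $\mu = \mu_y - \mu_x$ and $\Sigma = \Sigma_x + \Sigma_y$.
Among all linear combinations the AUC is maximized (up to a positive scalar)
by

$$\beta^\ast = (\Sigma_x + \Sigma_y)^{-1} (\mu_y - \mu_x).$$

With thousands of markers and tens of samples the pooled covariance cannot be
inverted.  The package therefore treats the defining moment equation $\mu =
\Sigma \beta$ as a linear regression with $p$ "observations" (the coordinates
of $\hat\mu$), design matrix $\hat\Sigma$, and no intercept, and solves the
elastic-net penalized problem

$$\hat\beta = \arg\min_\beta \; \|\hat\mu - \hat\Sigma \beta\|_2^2 +
\lambda \Big( \alpha \|\beta\|_1 + \tfrac{1 - \alpha}{2} \|\beta\|_2^2 \Big),$$

where $\hat\mu$, $\hat\Sigma$ are the plug-in sample estimates (class means;
class covariances with $m-1$ and $n-1$ denominators).  $\alpha = 1$ is the
lasso; the default $\alpha = 0.5$ keeps the elastic net's tendency to bring
groups of correlated markers into the model together, which is the regime
(many correlated informative genes) where this classifier outperforms
penalized logistic regression.  The label convention is fixed throughout:
class 1 is "diseased" and is the score-high class, which pins down the sign
of $\hat\mu$.

Assumptions worth stating plainly: the optimality of $\beta^\ast$ is a
two-class multivariate-normal result, and the plug-in estimates are ordinary
means and covariances, so the method inherits their sensitivity to outliers
and to heavy-tailed data.  The mixture simulation scenario (below) probes
exactly this kind of misspecification.

## Numerical choices

The solver is the package's own cyclic coordinate descent on the objective
exactly as written above — no intercept, no standardization of the
covariance "design" columns, and no $1/(2p)$ rescaling of the residual sum.
This matters: generic path solvers standardize by default and rescale their
penalties internally, which changes the solution (our test suite documents
the exact parameter mapping needed to make glmnet agree with the unscaled
objective, and uses glmnet only as an independent cross-check).  A
`standardize = TRUE` flag rescales design columns to unit root-mean-square
(and back-transforms the coefficients) as a sensitivity analysis.

* Coordinate update: $\beta_j \leftarrow S\big(2\, x_j'(y - X_{-j}\beta_{-j}),
  \lambda\alpha\big) / (2\, x_j'x_j + \lambda(1-\alpha))$ with $S$ the
  soft-threshold operator; consequently $\hat\beta = 0$ exactly when
  $\lambda \ge \lambda_{\max} = 2 \|\hat\Sigma'\hat\mu\|_\infty / \alpha$.
* Convergence: maximum absolute coordinate update below `tol = 1e-7`, at
  most `1e5` sweeps; non-convergence is an error carrying the last iterate.
  The tolerance is tight enough that the $\lambda \to 0$ fit reproduces the
  dense solve $\hat\Sigma^{-1}\hat\mu$ to $10^{-4}$ relative error whenever
  the covariance is well conditioned.
* Implementation: the solver works in Gram form ($G = \hat\Sigma'\hat\Sigma$
  and $q = \hat\Sigma'\hat\mu$ are computed once per design and shared by
  every fit along a path, across CV folds, and through the bisection), and
  interleaves an active-set Newton step — an exact solve of the stationarity
  system on the current support, accepted only when it lowers the objective
  — between coordinate passes.  Full coordinate passes remain authoritative
  for the KKT conditions, so the acceleration changes iteration counts, not
  solutions; on exchangeably correlated designs it cuts the dense-end sweep
  count by two orders of magnitude.
* Support: a coefficient counts as nonzero when $|\beta_j| > 10^{-10}$.
  This threshold is load-bearing for marker counting (nIMS/nTMS) and for
  the bisection below, so it is fixed package-wide.
* Degenerate input $\hat\mu = 0$: the zero vector is returned with a
  warning rather than an error, since it is the valid limit of the
  objective.

## Choosing the penalty strength

The candidate grid is anchored by model complexity rather than by raw
$\lambda$ values.  Let $r(\lambda)$ be the support size of the fit.  The
sparse end $\lambda_u$ is the penalty with $r = 1$; the dense end
$\lambda_l$ targets $r = 100$ markers, capped at $\min(p, m + n - 2)$ — the
rank of the pooled sample covariance, beyond which the path saturates before
the unpenalized problem turns singular (with the default $40+40$ training
samples the cap is 78).  Each anchor is found by bisection: starting from
$\lambda_{\max}$, halve $\lambda$ until $r(\lambda) \ge k$, then bisect the
bracket midpoint until $r = k$ or the relative bracket width falls below
$10^{-6}$.  Support sizes can jump along the path, so when $k$ is skipped
the nearer-support endpoint is returned (preferring the sparser side) and
flagged; callers see the achieved support in the result's attributes.  The
default grid holds 50 candidates, evenly spaced in $\log\lambda$.

Cross-validation maximizes the summed empirical AUC of held-out folds,

$$\mathrm{CV}_\lambda = \sum_{i=1}^{K} \widehat{\mathrm{AUC}}^{(i)}
\big(\hat\beta^{(-i)}_\lambda\big), \qquad
\widehat{\mathrm{AUC}} = \frac{1}{nm} \sum_{j}\sum_{i}
I\big(\beta' Y_j > \beta' X_i\big),$$

with $K = 3$ by default (appropriate for the 40-per-class sample sizes the
method targets; larger samples can raise `nfolds`).  Folds are stratified
within class so every held-out fold contains both classes, the grid is built
once on the full data and held fixed across folds, each fold's fit recomputes
the class summary statistics from scratch on the out-of-fold samples, and
score ties count as misorderings (the strict indicator above).  Ties in the
CV score are broken toward the larger $\lambda$, i.e. the sparser model.
The final model refits on all samples at the selected $\lambda$.

The empirical AUC is used strictly as printed, with a `ties = "half"`
(Mann–Whitney) option available.  Sensitivity at specificity $s$ uses the
smallest control-score order statistic with empirical specificity $\ge s$ —
no interpolation, since with 20 test controls specificity 0.95 is exactly
19/20 and interpolation would manufacture precision the data lack.  ROC
curves sweep the rule "score > threshold" over all distinct scores; the area
under the vertex path equals the half-tie empirical AUC.

## The penalized logistic baseline

`fit_penalized_logistic()` fits the elastic-net / lasso logistic regression
with glmnet (the standard tool for that standard model), with the intercept
unpenalized and excluded from support counts, and reports $\lambda$ on the
same unscaled (total log-likelihood) objective as the rest of the package.
Its candidate grid comes from glmnet's own data-driven $\lambda$ range on
the full training data, log-evenly respaced to the configured number of
candidates — mirroring the fixed-grid-on-full-data convention — and is then
tuned by exactly the same empirical-AUC CV score, so baseline comparisons
differ only in the fitted model, never in the tuning machinery.

## What the simulation generator emulates

`generate_normal_scenario()` mimics a screened microarray panel:

* Informative markers: $b$ independent blocks of $s$ markers
  ($b \in \{1,2,3\}$, $s \in \{5,20,40\}$ in the benchmark grid) with unit
  variances and exchangeable within-block correlation $\rho$ ($0.3$–$0.9$),
  zero correlation between blocks; cases centred at $+0.6$, controls at
  $-0.6$ on every informative marker.  The effect size is chosen so each
  single informative marker has design AUC $\Phi(1.2/\sqrt 2) = 0.80$.
* Noise markers pad the panel to 1000 total: half $N(0,1)$ and half
  $U[-1,1]$ (the floor goes to the Gaussian half when the count is odd),
  identically distributed in both classes.  Noise markers are appended
  after the informative block by default with positions recorded; a
  `randomize_positions` flag permutes columns for order-sensitivity checks.
* Sample sizes: $40 + 40$ training and an independent $20 + 20$ test set
  per replicate.

`generate_mixture_scenario()` contaminates the informative panel: each
sample draws its 50 informative markers (one exchangeable block, $\rho =
0.8$, the same $\pm 0.6$ centres) from the signal component with
probability 0.8 and from $N(0, I)$ otherwise.  This violates the normal
model under which the combination is optimal and checks robustness of the
plug-in estimates.

Replicate seeds are derived deterministically from a base seed (a fixed
integer hash, recorded per replicate), so every cell of a benchmark table is
individually reproducible.  Experiments report across-replicate **medians**
of test AUC, sensitivity at specificity 0.95, the number of true informative
markers selected (nIMS), and the total markers selected (nTMS).

What passing these benchmarks does *not* show: the generator draws from the
very model family the method assumes (plus a single contamination scenario),
with uncorrelated noise, no batch structure, no missingness, and
marker-independent scaling.  Real expression data violate all of these, so
the real-data pipeline (quantile normalization, log transform, moderated-t
screening, stratified splitting) is exercised on synthetic tables in the
test suite, and no claims are made here about results on any particular
external dataset.

## Preprocessing defaults

The expression pipeline mirrors common microarray practice: quantile
normalization across samples, then a log transform, then ranking markers by
absolute moderated $t$ (empirical-Bayes shrunken variances, computed by
limma) and keeping the top $k$ (1000 is the conventional panel size this
package is designed around).  The log base and offset are not dictated by
the
method; the defaults (base 2, offset 0 applied after normalization) are
stated assumptions, and an `ordinary_t` statistic is available since
ranking is the statistic's only consumer here.  Zero-variance markers under
the ordinary $t$ rank by the convention $|t| = \infty$ when the mean
difference is nonzero and $0$ otherwise, keeping the ranking deterministic.
Missing values are rejected, never imputed.  The stratified splitter sends
$\lfloor f \cdot n_{\text{class}} \rfloor$ samples of each class to
training and the remainder to testing — a fixed, testable rounding rule.

## Problem sizes used in the shipped checks

The shipped acceptance script runs each simulation cell at the benchmark
depth of 100 replicates (a five-cell sweep completes in about five minutes
on one core); the test suite's headline check uses a 50-replicate
desk-scale run, at which depth the across-replicate medians are still
stable to within the stochastic tolerances it asserts.

## Known limitations

* The covariance regression has $p$ observations and $p$ predictors, so
  memory and time grow as $p^2$; screening to ~1000 markers first is the
  intended workflow.
* Sample means and covariances are not robust; heavy contamination degrades
  the combination (by design, see the mixture scenario).  Robust or
  positive-definite covariance estimation is out of scope.
* Only two-class problems are supported, and the empirical-AUC CV score is
  coarse for very small samples (each fold AUC is a fraction over a small
  pair grid); a deviance-based CV score is a possible alternative hook, not
  implemented.
* The support-size bisection assumes the requested support is reachable on
  the path; requests beyond the covariance rank bound fail with an
  informative error rather than silently returning a denser model.
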