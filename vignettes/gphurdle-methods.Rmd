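---
title: "Methods: generalized Poisson hurdle regression in gphurdle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: generalized Poisson hurdle regression in gphurdle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gphurdle)
```

## The model and its assumptions

`gphurdle` models a non-negative integer response whose zero share and
dispersion both depart from the Poisson. Two independent processes generate
each observation. A binary process emits a zero with probability $w_i$;
otherwise the count comes from a zero-truncated generalized Poisson (GP2)
distribution:

$$\Pr(Y_i = 0) = w_i, \qquad
  \Pr(Y_i = j) = (1 - w_i)\,\frac{g(j;\mu_i,\alpha)}{1 - g(0;\mu_i,\alpha)},
  \quad j \ge 1,$$

with
$g(y;\mu,\alpha) = \left[\tfrac{\mu}{1+\alpha\mu}\right]^y
\tfrac{(1+\alpha y)^{y-1}}{y!}
\exp\!\left[-\tfrac{\mu(1+\alpha y)}{1+\alpha\mu}\right]$,
$E[Y] = \mu$ and $\mathrm{Var}[Y] = \mu(1+\alpha\mu)^2$ for the untruncated
GP2. Covariates enter through $\log \mu_i = x_i^\top\beta$ and
$\mathrm{logit}\, w_i = z_i^\top\delta$; the two parts may share covariates
or not. The dispersion parameter $\alpha$ is common across observations:
$\alpha > 0$ yields over-dispersion, $\alpha < 0$ under-dispersion, and at
$\alpha = 0$ the model is exactly the Poisson hurdle. With
$w_i = g(0;\mu_i,\alpha)$ the hurdle is inactive and the model collapses to
one-part GP regression. These two special cases are fitted as explicit
baselines (`fit_ml("ph", ...)`, `fit_ml("gp", ...)`) so that AIC
($-2\ell + 2p$, with $p$ the number of free parameters: $p+q+3$, $p+q+2$ and
$p+2$ respectively) compares all three on equal terms.

Key assumptions: observations are independent given covariates; the
dispersion is constant; the zero process is a pure Bernoulli hurdle (zeros
come only from the first process); and for $\alpha < 0$ the GP2 pmf is used
exactly as written, i.e. it assigns zero mass beyond the support point
$\max\{y : 1 + \alpha y > 0\}$ and therefore sums to slightly less than
one. We deliberately do **not** renormalize — the mass deficit is exposed
through `gp_mass_deficit()` so users can judge whether their $(\mu,\alpha)$
region is affected. The samplers, which must condition on the realizable
support, are the one place where the deficit is renormalized away.

## Estimation

**Maximum likelihood.** The log-likelihood splits into the zero and
positive branches; the GP2 pmf is always evaluated in log space
(`lgamma` for $y!$, softplus forms for $\log w$ and $\log(1-w)$), which is
stable for counts up to the order of $10^3$. Starting values are
moment-based: the count intercept at $\log \bar y^+$ (mean of positive
counts), remaining $\beta$ at zero, the zero intercept at the empirical
logit of the zero fraction, and $\alpha = 0.01$. Parameter values outside
the family ($1 + \alpha\mu_i \le 0$, or non-finite $\mu_i$) are assigned
the fixed penalty $10^{10}$ rather than raising an error, keeping the
simplex search unconstrained. If the search exhausts its iteration budget a
single restart is made from a deterministically jittered start (each
coordinate moved by 10% of its scale); determinism everywhere was preferred
over random restarts so that identical inputs always reproduce identical
fits.

**GMM.** With stacked covariates $X_i = (x_i^\top, z_i^\top)^\top$ the
moment conditions match the model-implied first two raw moments,

$$h(y_i, X_i, \theta) =
  \begin{pmatrix} X_i\,(y_i - g_{1i}) \\ X_i\,(y_i^2 - g_{2i})\end{pmatrix},
  \qquad
  g_{1i} = r_i \mu_i,\quad
  g_{2i} = r_i\,[\mu_i(1+\alpha\mu_i)^2 + \mu_i^2],$$

with hurdle factor $r_i = (1-w_i)/(1-e^{-\mu_i/(1+\alpha\mu_i)})$, and the
estimator minimizes $Q_n = h_n^\top W h_n$. Two conventions for the second
raw moment circulate — the bracket above, which is consistent with the GP2
variance, and a variant with $\mu(1+\alpha\mu)$ in place of
$\mu(1+\alpha\mu)^2$. We adopt the variance-consistent form as the default
because it is the one that brute-force pmf summation confirms
(`moment_g1_g2` is tested against $\sum_j j^2 \Pr(Y=j)$ to $10^{-6}$
relative error); the variant remains available as
`gmm_spec(g2_form = "linear")` for sensitivity analysis.

Two structural facts deserve emphasis:

* **Identification under shared covariates.** When $x = z$ the two copies
  of each moment row are identical, so there are only $2(p+1)$ distinct
  conditions for $2(p+1)+1$ parameters: the problem is under-identified as
  written, and even with $x \ne z$ the duplicated intercept rows make the
  moment covariance $\hat\Sigma$ singular. The default behaviour is kept
  faithful to this construction — minimization from the ML start finds a
  local solution — while `gmm_spec(augment_zero_moment = TRUE)` appends the
  zero-indicator conditions $z_i(1\{y_i=0\} - w_i)$, which restores full
  column rank of the Jacobian. `gmm_asymptotic_variance()` reports the
  numerical Jacobian rank precisely so this failure mode is visible.
* **Weight matrix.** The default is the identity (the simplest positive
  semi-definite choice); `"two_step"` rebuilds $W$ as the Moore–Penrose
  pseudo-inverse of $\hat\Sigma = n^{-1}\sum_i h_i h_i^\top$ at the
  first-stage estimate and re-minimizes once. The pseudo-inverse (SVD,
  singular values below $10^{-10}$ of the largest treated as zero) is used
  throughout because $\hat\Sigma$ is structurally singular, as noted above.
  The sandwich variance
  $\Gamma = (G^\top W G)^{-1} G^\top W \Sigma W G\,(G^\top W G)^{-1}$ is
  offered as a diagnostic, with $G$ from central finite differences on the
  sample moments (relative step $10^{-5}$).

GMM fits are started at the ML estimate by default; they report the GPHR
log-likelihood evaluated at the GMM solution as a quasi-AIC, labelled as
such, since AIC is a likelihood construct.

## The simplex optimizer

All fitting goes through one compiled Nelder–Mead implementation with the
standard coefficients: reflection $\eta = 1$, expansion $\gamma = 2$,
contraction $\xi = 1/2$, shrink $\kappa = 1/2$. The initial simplex places
vertex $i$ at the start point with coordinate $i$ displaced by
$0.05\max(|x_{0i}|, 1)$. Vertices are ordered by a stable sort (ties broken
by insertion order — the branch logic never depends on RNG state, so runs
are bit-reproducible). Iteration stops when the root-mean-square spread of
the objective over the $m$ best vertices falls below `eps`, when the
simplex diameter falls below `eps`$\cdot(1+\lVert\text{best}\rVert)$ (a
guard for flat objectives), or at `max_iter` (default 5000), in which case
`converged = FALSE` is returned along with the best point found.

The default `eps` is $10^{-10}$. An objective-spread criterion controls the
*value*, not the *argument*: near a quadratic optimum an objective spread
of $\varepsilon$ corresponds to a parameter error of order
$\sqrt{\varepsilon}$, so $10^{-10}$ is what resolves the argmin itself to
roughly $10^{-5}$. Benchmarks in the test suite hold the optimizer to
$10^{-4}$ on a convex quadratic and $10^{-3}$ on the Rosenbrock valley with
these defaults. Whether the spread averages over the $m$ best or all $m+1$
vertices is immaterial at this tolerance; we use the $m$ best.

## Inference

Bootstrap variance is the default for both estimators: $B$ (default 50)
with-replacement resamples of the rows, the estimator refitted on each
(initialized at the full-data estimate), and the empirical variance
$\frac{1}{B-1}\sum_b (\hat\theta^{*b} - \bar\theta^*)^2$ taken
componentwise. The resample size defaults to $n$; it is exposed as an
option but there is no standard reason to change it. A replicate whose
refit fails is redrawn (at most $5B$ attempts, count reported). For ML fits
the numerically differenced observed information is available as an
alternative (`ml_observed_info_se`). Wald intervals and two-sided p-values
use the normal reference; the degenerate cases $se = 0$ are mapped to
$p = 0$ (nonzero estimate) and $p = 1$ (zero estimate) explicitly.

In repeated-simulation checks at survey scale ($n = 500$, $B = 50$, 200
replicates) the 95% Wald intervals on the count-part coefficients cover the
truth at rates within a wide calibration band (85–99%); $B = 50$ is small
for precise variance estimation, which is the price the default pays for
speed on small datasets.

## The synthetic-data generator

`sim_scenario()`/`generate_counts()` draw covariates independently from
finite value sets and then sample the hurdle model exactly: a Bernoulli
zero with probability $w_i$, otherwise an inverse-CDF draw from the
zero-truncated GP2. Inverse-CDF (over the cumulative pmf capped at total
mass $1 - 10^{-12}$, hard ceiling $y = 10^6$) was chosen over rejection
sampling because rejection degenerates when $g(0)$ is large — exactly the
zero-heavy regime this package targets.

`earlike_scenario()` is the reference preset: $n = 190$, a frequency
covariate coded 1/2 and a place covariate coded 1/4 (equal probability,
independent), $\alpha = 0.28$, slopes $(0.63, 0.07)$ in the count part and
$(-0.71, -0.37)$ in the zero part. The two intercepts ($-0.406$ and
$1.901$) were calibrated once by solving the population equations over the
covariate grid so that the population zero share is $0.48$ and the marginal
mean is $1.6$ — the regime of a small ear-infection-style health survey:
roughly half the respondents report no events, and the marginal variance
(about 6) is nearly four times the mean. What the preset does *not*
emulate: covariate dependence (real survey covariates are correlated with
each other and with exposure), unequal category frequencies, and any
misspecification of the hurdle form itself. Passing recovery tests on these
simulations therefore demonstrates internal consistency of the estimators,
not robustness to real-data violations.

## Numerical choices collected

* GP2 pmf in log space; support truncation at $1 + \alpha y \le 0$ returns
  exact zeros; no renormalization of the $\alpha < 0$ mass deficit
  (diagnostic accessor instead); samplers condition on the realizable
  support.
* Cumulative-mass support cap $1 - 10^{-12}$ with a $10^6$ ceiling for
  summation and sampling tables.
* Infeasible-parameter penalty $10^{10}$ in all objectives.
* Pseudo-inverse tolerance: singular values below $10^{-10}$ of the
  largest.
* Finite differences: relative step $10^{-5}$ for the moment Jacobian,
  $10^{-4}$ for the observed-information Hessian.
* Optimizer: defaults $\eta=1,\gamma=2,\xi=1/2,\kappa=1/2$,
  `eps` $=10^{-10}$, `max_iter` $=5000$, initial step 5%.

## Problem sizes used by the test suite

The statistical checks run at desk scale, chosen to keep the full suite
within a few minutes while leaving Monte-Carlo error well below the
tolerances tested: samplers and moment validity at $n = 10^5$; parameter
recovery with 50 replicates at $n = 2000$ (bias within 3 Monte-Carlo SEs
for ML and identity-weight GMM with distinct covariates) and 20 replicates
each at $n \in \{500, 2000, 8000\}$ (RMSE monotone in $n$); bootstrap
calibration at $B = 2000$ on the sample mean and $B = 50$ Wald coverage
over 200 survey-scale replicates.

## Known limitations

* GMM columns of a published comparison cannot be reproduced exactly when
  the weight matrix and the handling of under-identification used there
  are not disclosed; with shared covariates the default GMM solution is a
  local one by construction.
* The dispersion parameter is global; covariate-dependent dispersion is out
  of scope.
* No offsets, formula interface, or interaction expansion: design matrices
  are taken as supplied (plus the intercept).
* Bootstrap intervals are plain Wald-with-bootstrap-SE; no BCa or
  studentized refinements.
* For strongly negative $\alpha$ the closed-form moments ignore the
  truncation deficit; the package reports the deficit but does not correct
  the moments.
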