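# gphurdle

Count outcomes in epidemiology and healthcare — numbers of infections,
clinic visits, adverse events — routinely violate the Poisson model in two
ways at once: the share of zeros is wrong (too many people with no events,
or too few), and the variance does not match the mean (over- or
under-dispersion). Models that fix one problem usually ignore the other.

`gphurdle` fits a **generalized Poisson hurdle regression** (GPHR) that
handles both simultaneously, together with the two natural baselines it
nests or extends — the Poisson hurdle (PH) and the one-part generalized
Poisson regression (GP) — so the three can be compared by AIC on the same
data. It is aimed at applied statisticians analysing small-to-moderate
survey or registry count data.

## The model

The positive counts follow a zero-truncated generalized Poisson (GP2)
distribution with pmf

```
g(y; mu, alpha) = [mu/(1+alpha*mu)]^y (1+alpha*y)^(y-1)/y! * exp[-mu(1+alpha*y)/(1+alpha*mu)]
```

which has mean `mu` and variance `mu (1+alpha*mu)^2`; `alpha > 0` gives
over-dispersion, `alpha < 0` under-dispersion, `alpha = 0` is Poisson. A
separate binary process produces zeros with probability `w`:

```
P(Y = 0) = w,      P(Y = j) = (1 - w) g(j) / (1 - g(0)),  j >= 1,
log(mu_i)   = x_i' beta      (count part),
logit(w_i)  = z_i' delta     (zero part).
```

Estimation is by maximum likelihood and by the generalized method of
moments (GMM), which matches the model-implied first two raw moments of Y
against the data through the quadratic form `Q_n = h_n' W h_n`. Both
objectives are minimized with a purpose-built Nelder–Mead simplex optimizer
(reflection 1, expansion 2, contraction 1/2, shrink 1/2). Standard errors
come from the bootstrap (default B = 50) or the numerically differenced
observed information; Wald intervals and p-values use the normal reference.

## Worked example

Simulate a survey-shaped dataset (190 subjects, two categorical covariates,
about half zeros, over-dispersed counts), fit the hurdle model, and compare
against the baselines:

```r
library(gphurdle)
d <- generate_counts(earlike_scenario(seed = 7))
d
#> count_dataset: n = 190, zeros = 104 (54.7%), mean = 1.447, var = 6.079

fit <- add_bootstrap_inference(fit_ml("gphr", d), d, B = 50, seed = 8)
fit
#> GPHR fit (ML): loglik = -291.7874, AIC = 597.5748, converged in 462 iterations
#>        estimate     se  ci_low ci_high p_value
#> alpha    0.2572 0.0912  0.0784  0.4360  0.0048
#> beta0   -0.2163 0.6228 -1.4370  1.0043  0.7283
#> beta1    0.4781 0.2829 -0.0765  1.0326  0.0911
#> ...

compare_models(fit, fit_ml("ph", d), fit_ml("gp", d))
#>   model estimator    loglik n_params      aic delta_aic
#> 1  gphr        ml -291.7874        7 597.5748  0.000000
#> 2    gp        ml -297.3862        4 602.7724  5.197637
#> 3    ph        ml -312.6806        6 637.3612 39.786375
```

`alpha = 0.26` (CI excluding zero) confirms over-dispersion; the hurdle
model beats the one-part GP by 5 AIC points and the Poisson hurdle by 40.
A GMM refinement starting from the ML solution is one call:
`fit_gmm(d, init = fit$theta)`.

The same pipeline runs from a shell on any CSV with a YAML config:

```sh
Rscript inst/cli/gphurdle.R simulate --seed 7 --n 190 --out sim.csv
Rscript inst/cli/gphurdle.R fit --config run.yml
```

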