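# gma — generalized model aggregation of published statistical findings

Published studies of one phenomenon rarely share a design: they regress
different covariate subsets, fit linear, logistic or ANOVA models,
discretize continuous variables, or report only effect sizes. Classical
meta-analysis can combine such studies only when they measure the same
effect the same way. `gma` implements **generalized model aggregation**:
the analyst declares a candidate data-generating process (a *meta-model*)

```
y = f(x, ε; β)
```

and its parameters β are estimated by *simulated replication* of every
prior study. Each study's reported statistics — regression coefficients,
MSE, R², ANOVA mean squares, effect sizes, between-study variances — are
treated as *signatures* γ̃ₗ of the process. For candidate parameters β the
package simulates covariates consistent with what study *l* reports, draws
responses from the meta-model, re-runs the study's own procedure hₗ on the
simulated data, and minimizes the weighted quadratic distance between the
published and the simulation-averaged signatures:

```
β̂ = argmin_β  e(β)' W e(β),     e_l(β) = γ̃_l − (1/S) Σ_s γ_l^s(β)
```

This is a method-of-simulated-moments / indirect-inference estimator whose
moments are whatever the literature happened to report. Because each
study's procedure is re-run faithfully — including its omitted variables
and discretizations — the systematic biases of the prior studies are
modeled rather than averaged, so the aggregate can recover a truth that
lies outside the range of all published coefficients. The weight matrix is
iterated toward the inverse covariance of the signature estimators
(efficient weighting); the package provides asymptotic and parametric
bootstrap confidence intervals, a χ² goodness-of-fit statistic (`chi0`), a
model-selection criterion (`MSC = chi0 + 2 dim β`), a leave-one-study-out
outlier diagnostic, a measurement-error extension, and seven synthetic
validation scenarios including a head-to-head comparison with
DerSimonian–Laird random-effects meta-analysis.

## Worked example

Three "published" studies each regress `y` on two of three correlated
covariates (the classic omitted-variable setting), reporting three
coefficients and an MSE apiece. The true process is
`y = 1 + x1 + x2 + x3 + N(0,1)`. Study 1's published signatures are badly
biased by the missing covariate:

```r
library(gma)
gen <- generate_scenario(scenario_config(1, seed = 42))
gen$studies[[1]]$empirical_signatures
#> intercept      b:x1      b:x2       mse
#>  1.107614  1.324281  1.323203  1.461518
```

Its slope estimates are ~1.32 — each coefficient has absorbed part of the
omitted covariate's effect. Aggregating all twelve signatures recovers the
generating process:

```r
fit <- gma_fit(gen$model, gen$studies, plan = simulation_plan(seed = 7, rounds = 2))
fit
#> Generalized model aggregation fit: 'linear scenario 1'
#>   3 studies, 12 signatures, 5 parameters (dof = 7)
#>       estimate     se  2.5 % 97.5 %
#> b0      1.0693 0.0743 0.9236 1.2150
#> b_x1    1.1268 0.0936 0.9434 1.3103
#> b_x2    1.0266 0.1006 0.8294 1.2239
#> b_x3    0.9001 0.0993 0.7055 1.0948
#> sigma   1.0261 0.0709 0.8872 1.1651
#>   chi0 = 3.281 on 7 dof (p = 0.858); MSC = 13.281
```

Every true parameter (all equal to 1) is inside its 95% interval, and the
goodness-of-fit statistic is consistent with its χ²₇ reference — the
meta-model reproduces the literature it aggregates. `wald_test()`,
`bootstrap_ci()`, `loo_influence()` and `compare_meta_models()` operate on
the same fit; `run_scenario()` repeats the whole generate–fit–score cycle
to measure bias, spread and interval coverage. The methods vignette
(`vignettes/gma-methods.Rmd`) documents the model, the weighting
iteration, the numerical choices, and each validation scenario.

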