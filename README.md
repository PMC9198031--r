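# dclr: distributed conditional logistic regression for multi-site binary outcomes

`dclr` estimates covariate–outcome associations (log odds ratios) for a
binary outcome observed across many clinical sites when two constraints
bind at once: patient-level data cannot leave the sites, and baseline
event rates differ between sites.  It is aimed at biostatisticians and
clinical-informatics teams running federated analyses across hospital or
claims-data networks.

## The model and the estimators

The underlying model is site-stratified logistic regression,

    logit Pr(y = 1 | x, site k) = alpha_k + beta' x,

with a free intercept per site and shared coefficients `beta`.  Rather
than estimating hundreds of nuisance intercepts, `dclr` conditions them
away: every discordant (case, control) pair within a site contributes

    l_m(beta) = -log(1 + exp(-beta' d_m)),   d_m = x_case - x_control,

the conditional probability that the observed case is the case — a
quantity free of `alpha_k`.  A site's pairwise log-likelihood sums over
its `D_k = n_cases * n_controls` pairs; the **pooled** estimator
(`fit_pooled`, the gold standard requiring all data in one place)
maximizes the sum across sites.

The distributed **dCLR** estimator (`fit_dclr`) reproduces the pooled
analysis with exactly one round of aggregate communication:

1. every site fits its own pairwise model and broadcasts the coefficient
   estimate (`emit_initial`); the coordinator averages them into an
   anchor `beta_bar`;
2. every site broadcasts its gradient and Hessian at the anchor
   (`emit_derivatives`); a lead site maximizes the surrogate objective —
   its own likelihood plus linear and quadratic correction terms that
   give the surrogate the pooled gradient at the anchor.  By default
   every site acts as lead and the results are combined by
   inverse-variance averaging.

Comparators and inference: site-wise fits (`fit_local`), fixed-effect
inverse-variance meta-analysis (`fit_meta`), a U-statistic sandwich
variance (`sandwich_variance`), and a within-site bootstrap
(`bootstrap_ci`).  A synthetic multi-site generator
(`generate_multisite`) and a simulation harness (`run_scenario`,
`summarize_scenario`, `plot_violins`) quantify how each method tracks the
gold standard as events become rare.  A file-based CLI (`dclr_cli`,
installed script in `inst/cli/dclr`) runs each protocol step as a
separate process so a real multi-party deployment exchanges only payload
files.

## Worked example

Twenty heterogeneous sites, ~1000 patients each, median event rate 5%,
true effects `beta = (1.0, 0.5)`:

```r
library(dclr)
cfg <- scenario_config(K = 20, prevalence_median = 0.05, seed = 2026)
ms  <- generate_multisite(cfg)
ms
#> <multisite_data: 20 sites, 19821 subjects, 971 cases (prevalence 0.049)>

pooled <- fit_pooled(ms)          # gold standard: needs all the data
pooled
#> Pairwise conditional logistic fit (method: pooled)
#>    estimate     se     or
#> x1   0.9960 0.0022 2.7075
#> x2   0.5416 0.0037 1.7187
#> converged: TRUE (6 iterations)

dclr_fit <- fit_dclr(ms)          # one round of aggregates only
meta_fit <- fit_meta(lapply(ms$sites, fit_local))
cbind(pooled = coef(pooled), dclr = coef(dclr_fit), meta = coef(meta_fit))
#>       pooled      dclr      meta
#> x1 0.9960384 0.9960391 0.9698894
#> x2 0.5415905 0.5415950 0.5409616
```

The distributed estimate matches the pooled one to the sixth decimal,
while meta-analysis already drifts at a 5% event rate.  The `se` column
above is the model-based (composite-likelihood) value and is only used
for weighting; calibrated intervals come from the sandwich:

```r
se <- sqrt(diag(sandwich_variance(pooled, ms)))
round(cbind(estimate = coef(pooled), se = se,
            lower = coef(pooled) - 1.96 * se,
            upper = coef(pooled) + 1.96 * se), 4)
#>    estimate     se  lower  upper
#> x1   0.9960 0.0422 0.9133 1.0788
#> x2   0.5416 0.0761 0.3924 0.6908
```

Both intervals cover the simulation truths (1.0 and 0.5).

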