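# gllph

Parametric proportional-hazards (PH) survival modelling with a
**generalized log-logistic (GLL) baseline hazard**, for right-censored
time-to-event data — the setting of cancer survival studies where the
hazard may rise and then fall (unimodal), a shape the classical
exponential/Weibull/Gompertz PH baselines cannot express.

The GLL distribution has hazard and cumulative hazard

    h0(t) = alpha * k * (k t)^(alpha-1) / (1 + (eta t)^alpha)
    H0(t) = (k/eta)^alpha * log(1 + (eta t)^alpha)

with rate `k > 0` and shapes `alpha, eta > 0`. It nests the Weibull
(`eta -> 0`) and the log-logistic (`k = eta`), accommodates constant,
monotone, V-shaped and unimodal hazards, and — unlike the plain
log-logistic — is *closed under the PH operation*: multiplying the hazard
by `exp(x'beta)` yields another GLL with rate `k* = k * exp(x'beta)^(1/alpha)`.
The full PH model is `h(t|x) = h0(t) exp(x'beta)` (no intercept), so hazard
ratios `HR = exp((x1 - x2)'beta)` are time-constant.

The package provides, for audiences doing applied survival analysis or
methods work:

* GLL distribution functions (`dgll`, `pgll`, `qgll`, `rgll`, `hgll`,
  `Hgll`) and a uniform baseline interface (`hazard()`, `cum_hazard()`,
  `surv()`, `cdf()`, `dens()`, `quantile()`, `inv_cum_hazard()`) over the
  GLL, exponential, Weibull and Gompertz families;
* the right-censored PH log-likelihood with analytic GLL score, and
  maximum likelihood via `fit_ph_mle()` (broom-style `tidy()`/`glance()`);
* Bayesian inference via `sample_posterior()` — adaptive random-walk
  Metropolis with gamma(10, 10) baseline priors and N(0, precision 0.001)
  coefficient priors — with `summarize_posterior()`, `diagnose()`
  (Gelman–Rubin PSRF/MPSRF, Geweke z, effective sample size), `dic()` and
  `compare_models()` for DIC ranking, and `posterior_hazard_ratio()`;
* an inversion-method simulator of censored GLL-PH datasets
  (`sim_ph_data()`) and a replicated recovery harness (`run_sim_study()`)
  reporting bias, MSE, naive SE and coverage probability;
* the total-time-on-test transform (`ttt_statistic()`, `plot_ttt()`) for
  pre-fit hazard-shape diagnosis, plus `autoplot()` trace/density/
  running-mean/ACF panels;
* a bundled larynx-cancer dataset (`larynx_data()`, 87 patients, tumour
  stages I–IV, times in months).

See `vignettes/gll-ph-methods.Rmd` for the model, the sampler, all
numerical conventions, and known limitations.

## Worked example: larynx-cancer survival by tumour stage

```r
library(gllph)

d <- larynx_data()           # 87 subjects; stage expanded to stage2/3/4 dummies
fit <- sample_posterior(d, family = "gll",
                        config = mcmc_config(n_chains = 3, n_iter = 8000,
                                             n_burn = 2000, thin = 5, seed = 1))
summarize_posterior(fit)[, c("parameter", "mean", "sd", "q2.5", "q97.5", "p_positive")]
#>   parameter   mean     sd   q2.5 q97.5 p_positive
#> 1 k          0.353 0.0810  0.219 0.534      1
#> 2 alpha      1.53  0.212   1.16  1.98       1
#> 3 eta        0.866 0.240   0.458 1.39       1
#> 4 stage2    -0.215 0.452  -1.15  0.611      0.326
#> 5 stage3     0.336 0.327  -0.305 0.975      0.845
#> 6 stage4     1.20  0.384   0.414 1.93       0.999
```

The baseline (stage I) hazard has `alpha > 1` and sizeable `eta`, i.e. a
non-monotone shape; stage IV carries a posterior log-hazard-ratio of about
1.2 against stage I — `P(beta > 0 | data) = 0.999`, a clearly elevated
mortality — while stage II is indistinguishable from stage I. The
corresponding hazard ratio posterior:

```r
posterior_hazard_ratio(fit, x1 = c(0, 0, 1), x2 = c(0, 0, 0))
#>   mean   sd   q2.5 median q97.5
#> 1 3.56 1.37   1.51   3.36  6.86
```

a stage-IV patient dies at roughly 3.6 times the stage-I rate, with 95%
credible interval (1.5, 6.9). Convergence checks (`diagnose(fit)`) show
PSRF at most 1.01 and ESS of 392–719 for all six parameters, and
`dic(fit)` gives DIC = 298 with about 4.3 effective parameters.

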