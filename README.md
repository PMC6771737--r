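# semflm

Hierarchical Bayesian structural equation models (SEMs) for age- and
sex-structured binomial vital rates — survival, reproduction and twinning
across six age–sex classes — in which one or two latent yearly
*environmental axes* carry the shared temporal covariation, and the first
axis decomposes into density dependence, a temporal trend and climate.
Climate enters either as a scalar covariate (e.g. winter NAO) or as a
distributed-lag **functional linear model (FLM)**: a smooth
lag-coefficient function `f_c(w)` over 42 fortnightly (or 19 monthly)
windows, built on a cubic regression spline basis, letting the data locate
the critical climate window instead of fixing it a priori.

The package is aimed at population ecologists and biostatisticians who
want to fit, check and compare these models on yearly demographic panels:

* **Model.** For year `t`, the first axis is
  `e(t) = D_t − Σ_w f_c(w) C_tw − α_t t − ε_e[t]`, with `D_t` the log10
  August population count and `C_tw` centered climate anomalies.
  Thresholded survival submodels are flat in `e` below a threshold `θ`
  and decline above it (`logit S = β0 + β_t t − β_e (e − θ)` for
  `e ≥ θ`); fecundity submodels are logistic in `e`, three of them also
  loading on a second axis `ε_f` (unit SD, correlated with `ε_e`).
* **Inference.** An adaptive Metropolis-within-Gibbs sampler (C++ core,
  bit-reproducible given a seed) with ridge-aware proposals for the
  model's latent-variable geometry.
* **Evaluation.** Leave-one-year-out cross-validation with the random
  year effects integrated out by Monte Carlo (marginal elpd, compared on
  the deviance scale `−2 Δelpd`), Bayesian R² of the first axis,
  posterior predictive checks, observed-vs-predicted summaries, and
  second-axis covariate screening.
* **Synthetic data.** A ground-truth generator
  (`truth_scenario()` / `simulate_dataset()`) emulating a 30-year island
  sheep study — density series, daily weather with seasonal + anomaly
  structure, latent axes, and demographically book-kept binomial panels —
  so the whole pipeline is testable end to end.

## Worked example

Simulate the default 30-year study, fit the two-axis baseline SEM under
the desk-scale MCMC profile, and compare the fit against the known truth:

```r
library(semflm)

scn  <- truth_scenario(seed = 42)          # known ground truth
ds   <- simulate_dataset(scn)
spec <- model_spec(ds$panel, "baseline_2axis")
post <- run_mcmc(ds$panel, spec, mcmc_config(seed = 7))

d   <- mcmc_diagnostics(post)
med <- posterior_median_params(post)
cat("max split-Rhat:", round(max(d$rhat, na.rm = TRUE), 3), "\n")
cat("alpha_t:", round(med$alpha_t, 4), "(truth 0.015)\n")
cat("sigma_e:", round(med$sigma_e, 3), "(truth 0.1)\n")
r2 <- bayes_r2(post, ds$panel, spec)
cat("axis R2:", round(r2$median, 2),
    sprintf("(%.2f-%.2f)\n", r2$lower, r2$upper))
```

```
max split-Rhat: 1.026 
alpha_t: 0.0163 (truth 0.015)
sigma_e: 0.107 (truth 0.1)
axis R2: 0.72 (0.50-0.85)
```

The sampler converges (split-Rhat ≈ 1), the axis trend and year-effect
SD land on the truth, and the axis R² is the posterior share of
first-axis variance explained by density and trend. Fitting an FLM
variant only changes the spec:

```r
scn_f  <- truth_scenario(params = soay_truth(climate = "flm"), seed = 42)
ds_f   <- simulate_dataset(scn_f)           # daily weather -> windows -> anomalies
spec_f <- model_spec(ds_f$panel, "flm_climate", climate = ds_f$climate)
post_f <- run_mcmc(ds_f$panel, spec_f, mcmc_config(seed = 7))
g_med  <- apply(post_f$draws[, grep("^gamma", colnames(post_f$draws))], 2, median)
cor(eval_flm(spec_f$term, g_med), eval_flm(spec_f$term, ds_f$truth$gamma))
```

```
[1] 0.98
```

The posterior-median lag function reproduces the two-lobe truth (negative
autumn–winter effect in the focal year, weaker positive lobe in the
previous spring) almost exactly in shape.

A file-based pipeline (`cmd_simulate()`, `cmd_fit()`, `cmd_cv()`,
`cmd_report()`, plus the thin CLI in `inst/scripts/semflm-cli.R`) writes
each stage's CSV/YAML/JSON artifacts with manifests for bit-identical
reruns. See the methods vignette (`vignettes/semflm-methods.Rmd`) for the
model, priors, sampler design and the generator's scope.

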