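---
title: "Latent environmental axes and distributed-lag climate effects for structured vital rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent environmental axes and distributed-lag climate effects for structured vital rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(semflm)
```

## The problem

Vital rates of age- and sex-structured populations — survival,
reproduction, twinning — tend to rise and fall together across years:
good years are good for everyone. Modelling each rate's environmental
drivers separately ignores this covariation and multiplies the number of
driver–window choices to be made. `semflm` implements a demographic
structural equation model (SEM) in which the temporal covariation of
eleven binomial vital-rate submodels (six age–sex survival classes, three
ewe reproduction classes, two twinning classes) is carried by one or two
*latent yearly environmental axes*, and in which the first axis is then
decomposed into the effects of population density, a temporal trend, and
climate. Climate can enter as a conventional scalar covariate (winter
NAO, March precipitation) or as a *functional linear model* (FLM): a
distributed-lag term whose coefficient varies smoothly over 42
fortnightly (or 19 monthly) lag windows spanning the 19 months before the
end of the demographic year, so that the data decide both the critical
window and the sign of the effect.

## The model

For study year `t` (centered index) and density `D_t` (log10 August
population count), the first environmental axis is

    e(t) = D_t - climate(t) - alpha_t * t - eps_e[t]

where `climate(t)` is `0` (baseline), `beta_m * M_t` (scalar covariate),
or `sum_w f_c(w) * C_tw` (FLM) with `C_tw` the centered climate anomaly
in lag window `w`. The residual year effects `eps_e[t]` are normal with
standard deviation `sigma_e`; under the two-axis model they pair with
second-axis effects `eps_f[t]` (unit SD) in a bivariate normal with
correlation `rho_ef`.

Survival submodels (except male lamb survival, where no threshold is
supported by the data the design emulates) use a piecewise ("threshold")
linear predictor, flat below a threshold `theta` — at low density the
environment hardly moves survival — and declining above it:

    logit S = beta0 + beta_t * t                          e(t) <  theta
    logit S = beta0 + beta_t * t - beta_e * (e - theta)   e(t) >= theta

The two branches agree exactly at `e = theta`, which is a tested
invariant. Fecundity submodels and male lamb survival are plain logistic
(`logit R = beta0 + beta_t * t - beta_e * e`), and the three submodels
with fecundity variation beyond the first axis (lamb reproduction, adult
reproduction, adult twinning) additionally carry `+ beta_f * eps_f[t]`.
All submodels are binomial with the coefficient term included, so
predictive densities are proper log probabilities.

The lag-coefficient function `f_c(w)` uses a cubic regression ("cr")
spline basis in its value parameterization: eight knots spread evenly
over the window range, basis built so that the coefficients *are* the
values of `f_c` at the knots, with natural (zero second derivative) end
conditions. This makes priors on the coefficients directly interpretable
and gives the exact interpolation property `f_c(knot_j) = gamma_j` that
the test suite checks against `stats::splinefun(method = "natural")` as
an independent oracle. No smoothing penalty is estimated: with 8 knots
over 42 windows the fit is a fixed-rank spline regularized only through
the coefficient prior.

## Identifiability conventions

Two latent-variable scale ambiguities must be pinned down:

* **Second axis.** `beta_f * eps_f` is invariant to rescaling; we fix
  `sd(eps_f) = 1`, estimate the three loadings freely, and resolve the
  sign by constraining the adult-reproduction loading positive
  (Half-Normal(1) prior).
* **First axis sign.** Because density enters the axis with unit
  coefficient, the axis sign is formally identified, but a mirror mode
  (all loadings negative, year effects reconstructing a reflected axis
  at roughly twice the year-effect SD) exists as an inferior local
  optimum. Chains are initialized with all loadings at +3 — the
  model's sign convention, under which rising density depresses vital
  rates — which keeps them in the correct basin (see the sampling
  section for the companion initialization of the year-effect SD).

## Priors

Defaults (all proper, weakly informative on the logit scale):

| block | prior | rationale |
|---|---|---|
| intercepts `beta0` | N(0, 1.5²) on the rate-logit at mean density | see below |
| trends `beta_t`, `alpha_t` | N(0, 1) | per-year changes are small |
| loadings `beta_e` | N(0, 10²) | logits per log10-density unit |
| thresholds `theta` | Uniform over central 90% of observed `D_t` | proper, data-scaled support |
| `sigma_e` | Half-Normal(1) | year effects well below 1 on the axis scale |
| `rho_ef` | Uniform(−1, 1) | unconstrained correlation |
| `beta_f` | N(0, 1); Half-Normal(1) for adult reproduction | unit-SD second axis |
| `beta_m`, `gamma` | N(0, 1) | standardized covariate / anomaly scale |

Density deliberately enters un-standardized (its unit coefficient anchors
the axis scale), so the *raw* intercept of a non-thresholded submodel is
an extrapolation to axis value zero and can legitimately sit in the
teens. The intercept prior therefore applies to the *centered* intercept
`beta0 - beta_e * mean(e)` — the rate at average observed density — for
non-thresholded submodels, and directly to the (already at-threshold)
intercepts of thresholded ones. The threshold prior is likewise made
proper and fixed by evaluating "the central 90% range of the fixed part
of the axis" at the density series itself (the fixed part with zero
trend and no climate), computed once at model construction. Setting
`beta0 = "flat_prob"` in `default_priors()` swaps the intercept prior
for a uniform prior on the success probability (logistic density on the
logit scale), which is what the conjugate Beta-Binomial checks use.

## Sampling

`run_mcmc()` is an adaptive random-walk Metropolis-within-Gibbs sampler
written in C++ with all randomness drawn from the R RNG (runs are
bit-reproducible given the seed). During the first half of burn-in every
free parameter is updated singly, each with its own step size adapted
toward 0.44 acceptance; for the rest of the run parameters move in
blocks — per-submodel fixed effects, the axis/climate coefficients, the
variance/correlation pair, the second-axis loadings, and each year's
effect pair jointly — with the per-coordinate scales learned in phase one
and a per-block multiplier adapted toward 0.234 (0.44 for scalar blocks).
Adaptation stops at the end of burn-in. Likelihood evaluation is
incremental: a proposal only recomputes the panel cells it can affect.

Four devices address the strong posterior ridges and reflection modes
this model contains:

1. **Centered intercepts.** The sampler state stores
   `beta0 - beta_e * mean(e)` for non-thresholded submodels (raw
   intercept and loading are nearly collinear because the axis hovers
   around its mean); draws are transformed back to raw intercepts before
   being returned.
2. **Axis-coefficient ridges.** Prior-only blocks move `alpha_t`,
   `beta_m` or a single `gamma` component together with all first-axis
   year effects such that every `e(t)` is left exactly invariant; only
   the year-effect prior resists the move. These are symmetric linear
   proposals, so Metropolis ratios are unaffected.
3. **Loading/second-axis ridge.** A companion move shifts
   `eps_f[t] += delta * (e(t) - mean(e))` and each loaded submodel's
   `beta_e += beta_f * delta`, which leaves every linear predictor
   invariant; the proposal coefficients involve only unmoved
   coordinates, so the move is again symmetric.
4. **Second-axis sign flip.** The likelihood is exactly invariant under
   jointly negating `beta_f`, `eps_f` and `rho_ef`; the positivity
   constraint on the adult-reproduction loading breaks the symmetry but
   leaves a reflected pseudo-mode (that loading pinned near zero, the
   rest negated) reachable during burn-in. A deterministic involution
   move — negate the unconstrained loadings, the correlation and every
   `eps_f` — is attempted once per sweep; the priors are exactly
   invariant under it, only the constrained submodel's likelihood enters
   the acceptance ratio, and being its own inverse it is a valid
   Metropolis proposal. The analogous first-axis mirror mode (all
   loadings negative, year effects reconstructing a reflected axis) is
   not an exact symmetry — density anchors the axis — and is avoided by
   initialization: loadings start at +3 (the sign convention), the
   year-effect SD starts small (0.1) so the likelihood anchors the axis
   before the variance opens up, and intercepts start at the pooled
   empirical logits.

The default *desk* profile (3 chains × 5×10⁴ post-burn-in iterations,
10⁴ burn-in, thinning 25) retains 6000 draws and fits the default
30-year panel in seconds; `paper_mcmc_config()` reproduces the original
study protocol (2 chains × 6×10⁶ iterations, 10⁵ burn-in, thinning
2000 — also 6000 retained draws) for users with hours to spend.
Convergence is summarized by split-Rhat and an initial-positive-sequence
effective sample size (`mcmc_diagnostics()`), with parameters above 1.05
flagged.

## The synthetic study system

No field data ship with the package; `truth_scenario()` defines a fully
known ground truth that emulates the study design the model was built
for: 30 years of an island sheep population of about 600 animals
(log10 density mean 2.78, stationary SD 0.12, AR(1) mean reversion 0.6 —
density is exogenous because the inferential model conditions on it),
six age–sex classes of roughly equal share setting survival trial counts
of ~100 per class-year, and demographic bookkeeping for fecundity trials:
reproduction trials are the surviving ewes of each class, yearling
twinning trials the ewes that reproduced as lambs, adult twinning trials
the yearling and adult reproducers. This makes yearling twinning
naturally rare — many zero-trial or zero-success years — as in the real
population. True loadings span 1–5 logits per log10-density unit,
thresholds sit ~0.3 SD below mean density (about a third of years in the
resource-rich flat regime), `alpha_t = 0.015`/yr accumulates to ~0.45
log10 units over the study, `sigma_e = 0.1`, `rho_ef = 0.3`.

Daily weather is a seasonal sinusoid plus an anomaly drawn once per
calendar fortnight (SD 2) plus daily noise, with a configurable missing
fraction; `simulate_axes()` consumes the *aggregated, centered* climate
matrix produced by the same `interpolate_missing()` →
`aggregate_windows()` → `center_windows()` pipeline the fit uses, so the
true FLM effect is exactly expressible in the fitted basis. The default
truth `f_c` is the spline interpolant of a two-lobe curve — a positive
lobe in late winter/spring of the prior year (window 6) and a stronger
negative lobe over autumn–winter of the focal year (window 27) — giving
a climate contribution SD of ~0.3 on the axis scale;
`winter_lag_effect()` provides a single strong winter lobe for
model-ranking experiments.

What the generator does *not* emulate: individual heterogeneity and
mark–recapture observation error (the emulated study knows nearly all
fates), density feedback from simulated survival, spatially structured
weather, and observation error in density. Passing recovery tests
therefore show that the inference machinery is faithful to this model
class at realistic sizes — not that the model is right for any
particular field system.

## Evaluation machinery

*Cross-validation.* `loyo_elpd()` refits the model once per held-out
year (cluster cross-validation; the held-out year's density and climate
stay available as covariates) and computes the *marginal* expected log
predictive density: for each retained draw, `M` fresh year-effect pairs
are drawn from their fitted law and the held-out year's 11-submodel
joint likelihood is averaged over them, combined by log-sum-exp —
conditioning on fitted random effects would be optimistic. The Monte
Carlo standard error comes from the spread of the per-draw averages
(delta method on the log), which respects the correlation of the `M`
samples within a draw. Model comparisons are reported on the deviance
scale, `-2 (elpd_A - elpd_B)`, negative favouring A. Refits failing
their own Rhat check are flagged per year, never silently included.
`folds` allows a reduced CV over a subset of years; comparisons remain
valid when both models use the same folds.

*Bayesian R².* Per draw, `Var_years(fixed part of e) / (Var_years(fixed
part) + sigma_e^2)` — the residual term is the first-axis year-effect
variance, matching a reading of "variance explained by the fixed
effects"; the second axis is deliberately not part of this summary.
Sample variance uses the usual n−1 denominator; a constant fixed part is
an error, not R² = 0.

*Posterior predictive checks.* Cell-wise mid-p tail probabilities
`Pr(rep > obs) + 0.5 Pr(rep = obs)` over replicated successes, flagged
outside [0.025, 0.975]; the mid-p convention keeps the 5% flag rate
approximately calibrated for discrete counts. Zero-trial cells are
reported as not applicable.

## Numerical choices and degenerate inputs

* Missing weather days are filled by linear interpolation on the date
  axis (ends extended with the nearest observation); at the few-percent
  missingness this is built for, the downstream fortnightly means are
  insensitive to the interpolant. Interpolated values never leave the
  range of their bracketing observations.
* Fortnight windows are fixed 14-day blocks anchored at 1 January of the
  prior year; the 42nd block is truncated at 31 July and averages only
  its available days. Window counts are invariant to leap years.
* Centering a single-year matrix, re-centering, evaluating the spline
  outside the knot span, `successes > trials`, and a covariance that is
  not positive definite are all errors, not silent repairs. Zero-trial
  cells contribute exactly zero likelihood and stay in the panel so the
  year indexing remains rectangular.
* `sigma_e = 0` is legal in the generator (year effects identically
  zero) but outside the prior support of the fitted model.

## Problem sizes used by the tests

The test-suite and acceptance-script sizes are the package's validation
design: recovery and FLM-recovery checks use 10 replicate 30-year panels
each under the desk MCMC profile; the model-ranking check uses 10
replicates of a reduced cross-validation (10 of the 30 years held out in
turn) with a shortened refit protocol (2 chains × 1.5×10⁴ iterations,
thinning 15), `M = 50` and `S = 1000`; conjugate checks use the exact
Beta and Beta-Binomial laws as oracles; the predictive-calibration check
replicates data from the fitted model itself and uses 500 posterior
draws.

## Known limitations

* When the climate term dominates axis variance, a soft ridge links the
  FLM amplitude, `sigma_e`, and the loadings; the *shape* of `f_c` is
  recovered cleanly (correlation with truth near 1) but its amplitude
  can trade against the year-effect variance, and shortened chains show
  elevated Rhat along this direction. Long chains, or informative priors
  on `gamma`, tighten this.
* The second axis "turns on" slowly from a cold start: with loadings
  near zero the year effects feel no likelihood, and very short chains
  can leave the factor unexpressed. The desk profile is long enough on
  the default design; halved protocols are not.
* With very few study years (around ten) the 8-knot FLM cannot be
  learned out-of-sample and leave-one-year-out ranking will favour the
  baseline even when a strong true effect exists — a property of the
  design, not a defect of the estimator.
* Leap days leave a one-day seasonal residual in the centered anomaly
  matrix (far below any anomaly signal, but not exactly zero).
* At the default study size the axis trend and year-effect SD are
  estimated with posterior coefficients of variation of roughly 30–40%:
  the trend signal `alpha_t * t` is small against `sigma_e`, and the
  year effects carry measurement noise of a few hundredths per year.
  Posterior intervals are calibrated (simulation-checked), but point
  estimates of `alpha_t` and `sigma_e` scatter accordingly across
  replicate data sets; recovering them to much tighter relative error
  would require a stronger trend, a larger year-effect variance, or a
  longer study than the default design provides.
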