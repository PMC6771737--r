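# Shared fixtures: a one-submodel toy design (conjugate checks), random
# parameter generators for property tests, and a cached small fit reused
# across evaluation tests.

toy_submodels <- function() {
  data.frame(id = 1L, name = "p", process = "reproduction",
             age_class = "adult", sex = "F", thresholded = FALSE,
             second_axis = FALSE, stringsAsFactors = FALSE)
}

toy_panel <- function(n, k, years = seq_along(n) + 2000L) {
  demographic_panel(years, rep(0, length(n)), matrix(as.integer(n), 1),
                    matrix(as.integer(k), 1), toy_submodels())
}

# intercept-only model: uniform prior on the success probability, all
# other parameters fixed so the posterior is Beta(1 + sum k, 1 + sum(n-k))
intercept_only_spec <- function(panel) {
  model_spec(panel, "baseline_1axis",
             priors = default_priors(beta0 = "flat_prob"),
             fixed = c(beta_t.p = 0, beta_e.p = 0, alpha_t = 0, sigma_e = 1,
                       setNames(rep(0, length(panel$years)),
                                paste0("eps_e.", panel$years))))
}

# random valid parameter set for the canonical 11-submodel design
random_params <- function(submodels = soay_submodels(),
                          theta_range = c(2.6, 2.96), two_axis = TRUE,
                          gamma = NULL, beta_m = NULL, n_years = 0) {
  S <- nrow(submodels)
  vital_params(
    submodels,
    beta0 = rnorm(S, 0, 2), beta_t = rnorm(S, 0, 0.05),
    beta_e = rnorm(S, 2, 2),
    theta = runif(sum(submodels$thresholded), theta_range[1], theta_range[2]),
    beta_f = abs(rnorm(sum(submodels$second_axis), 0.5, 0.5)),
    alpha_t = rnorm(1, 0, 0.02), sigma_e = runif(1, 0.05, 0.4),
    rho_ef = runif(1, -0.8, 0.8),
    beta_m = beta_m, gamma = gamma,
    eps_e = if (n_years) rnorm(n_years, 0, 0.1) else NULL,
    eps_f = if (n_years && two_axis) rnorm(n_years) else NULL
  )
}

# random small demographic panel for likelihood oracles
random_panel <- function(n_years = 6, submodels = soay_submodels()) {
  S <- nrow(submodels)
  trials <- matrix(rpois(S * n_years, 40), S, n_years)
  trials[sample(length(trials), 3)] <- 0L
  p <- matrix(runif(S * n_years, 0.05, 0.95), S, n_years)
  succ <- matrix(rbinom(S * n_years, trials, p), S, n_years)
  rownames(trials) <- rownames(succ) <- submodels$name
  demographic_panel(2000L + seq_len(n_years),
                    rnorm(n_years, 2.78, 0.12), trials, succ, submodels)
}

# one shortened two-axis fit on default synthetic data, computed once per
# test run and shared across files that only need a plausible posterior
cached_env <- new.env()
cached_small_fit <- function() {
  if (is.null(cached_env$fit)) {
    scn <- truth_scenario(n_years = 15, seed = 901)
    ds <- simulate_dataset(scn)
    spec <- model_spec(ds$panel, "baseline_2axis")
    cfg <- mcmc_config(seed = 902)
    cached_env$fit <- list(ds = ds, spec = spec,
                           post = run_mcmc(ds$panel, spec, cfg))
  }
  cached_env$fit
}
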