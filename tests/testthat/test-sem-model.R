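sub11 <- soay_submodels()

test_that("the canonical submodel table satisfies the study design", {
  expect_silent(validate_submodels(sub11, canonical = TRUE))
  expect_equal(sum(sub11$thresholded), 5)
  expect_false(sub11$thresholded[sub11$name == "surv.lamb.M"])
  expect_equal(sub11$name[sub11$second_axis],
               c("repro.lamb", "repro.ad", "twin.ad"))
  bad <- sub11; bad$thresholded[2] <- TRUE
  expect_error(validate_submodels(bad, canonical = TRUE), "male lamb")
})

test_that("axis value is the stated arithmetic", {
  expect_equal(axis_value(2.0, 0, 0), 2.0)
  expect_equal(axis_value(2.5, 10, 0.01, 0, 0.05), 2.35)
  expect_equal(axis_value(c(2, 3), c(-1, 1), 0.1, c(0.2, 0.2), 0),
               c(2 - 0.2 + 0.1, 3 - 0.2 - 0.1))
})

test_that("thresholded predictors are continuous, flat below, declining above", {
  set.seed(21)
  p <- random_params()
  thr <- sub11[sub11$thresholded, ]
  for (i in seq_len(nrow(thr))) {
    th <- p$theta[[thr$name[i]]]
    lo <- linpred(thr[i, ], p, th - 1e-9, t = 2)
    at <- linpred(thr[i, ], p, th, t = 2)
    hi <- linpred(thr[i, ], p, th + 1e-9, t = 2)
    expect_equal(lo, at, tolerance = 1e-7)
    expect_equal(at, p$beta0[[thr$name[i]]] + p$beta_t[[thr$name[i]]] * 2)
    # below threshold the axis has no effect at all
    expect_identical(linpred(thr[i, ], p, th - 0.3, t = 2),
                     linpred(thr[i, ], p, th - 0.01, t = 2))
    if (p$beta_e[[thr$name[i]]] > 0) expect_lt(hi, at + 1e-12)
  }
})

test_that("hand-computed threshold example evaluates correctly", {
  p <- random_params()
  nm <- "surv.lamb.F"
  p$beta0[nm] <- 2; p$beta_t[nm] <- 0; p$beta_e[nm] <- 1.5; p$theta[nm] <- 2.2
  eta <- linpred(nm, p, e = 3.0, t = 0)
  expect_equal(eta, 0.8)
  expect_equal(plogis(eta), 0.6900, tolerance = 1e-4)
})

test_that("survival decreases monotonically in the axis above the threshold", {
  set.seed(3)
  p <- random_params()
  p$beta_e[] <- abs(p$beta_e)
  for (nm in sub11$name[sub11$thresholded]) {
    e <- seq(p$theta[[nm]], p$theta[[nm]] + 0.5, length.out = 50)
    eta <- linpred(nm, p, e, t = 0)
    expect_true(all(diff(eta) < 0))
  }
})

test_that("second-axis effects only touch the loaded submodels", {
  p <- random_params()
  expect_error(linpred("surv.lamb.F", p, 2.7, t = 0, eps_f = 0.5),
               "contract violation")
  eta0 <- linpred("repro.ad", p, 2.7, t = 0, eps_f = 0)
  eta1 <- linpred("repro.ad", p, 2.7, t = 0, eps_f = 1)
  expect_equal(eta1 - eta0, unname(p$beta_f["repro.ad"]))
})

test_that("log likelihood is the binomial log pmf with zero-trial cells inert", {
  pan <- toy_panel(10, 7, 2001)
  spec <- model_spec(pan, "baseline_1axis")
  par <- vital_params(toy_submodels(), beta0 = 0, beta_t = 0, beta_e = 0,
                      sigma_e = 1, eps_e = 0)
  expect_equal(log_likelihood(pan, par, spec),
               lchoose(10, 7) + 10 * log(0.5), tolerance = 1e-12)
  pan0 <- toy_panel(c(0, 0), c(0, 0))
  spec0 <- model_spec(pan0, "baseline_1axis")
  par0 <- vital_params(toy_submodels(), beta0 = 0, beta_t = 0, beta_e = 0,
                       sigma_e = 1, eps_e = c(0, 0))
  expect_equal(log_likelihood(pan0, par0, spec0), 0)
  # certain event: p ~ 1 with all successes
  pan1 <- toy_panel(10, 10, 2001)
  par1 <- vital_params(toy_submodels(), beta0 = 40, beta_t = 0, beta_e = 0,
                       sigma_e = 1, eps_e = 0)
  expect_equal(log_likelihood(pan1, par1, model_spec(pan1, "baseline_1axis")),
               0, tolerance = 1e-10)
})

test_that("log likelihood matches a direct binomial-pmf summation", {
  set.seed(17)
  for (r in 1:40) {
    pan <- random_panel()
    spec <- model_spec(pan, "baseline_2axis")
    par <- random_params(theta_range = spec$theta_range,
                         n_years = length(pan$years))
    ll <- log_likelihood(pan, par, spec)
    # independent direct summation from first principles
    cc <- rep(0, length(pan$years))
    e <- pan$density - cc - par$alpha_t * pan$t - par$eps_e
    direct <- 0
    for (i in seq_len(nrow(sub11))) {
      for (tt in seq_along(pan$years)) {
        n <- pan$trials[i, tt]; k <- pan$successes[i, tt]
        if (n == 0) next
        eta <- linpred(sub11[i, ], par, e[tt], pan$t[tt],
                       eps_f = if (sub11$second_axis[i]) par$eps_f[tt] else NULL)
        prob <- 1 / (1 + exp(-eta))
        direct <- direct + lchoose(n, k) + k * log(prob) +
          (n - k) * log1p(-prob)
      }
    }
    expect_equal(ll, direct, tolerance = 1e-10)
  }
})

test_that("log prior composes from independent blocks and guards support", {
  set.seed(9)
  pan <- random_panel(8)
  spec <- model_spec(pan, "baseline_2axis")
  par <- random_params(theta_range = spec$theta_range, n_years = 8)
  lp <- log_prior(par, spec)
  expect_true(is.finite(lp))
  # per-block oracle
  ec <- spec$axis_center
  b0c <- par$beta0
  nt <- !sub11$thresholded
  b0c[nt] <- b0c[nt] - par$beta_e[nt] * ec
  s <- par$sigma_e; r <- par$rho_ef
  Sig <- matrix(c(s^2, r * s, r * s, 1), 2)
  yearp <- sum(vapply(1:8, function(t) {
    x <- c(par$eps_e[t], par$eps_f[t])
    -log(2 * pi) - 0.5 * log(det(Sig)) -
      0.5 * drop(x %*% solve(Sig) %*% x)
  }, numeric(1)))
  oracle <- sum(dnorm(b0c, 0, 1.5, log = TRUE)) +
    sum(dnorm(par$beta_t, 0, 1, log = TRUE)) +
    sum(dnorm(par$beta_e, 0, 10, log = TRUE)) -
    5 * log(diff(spec$theta_range)) +
    dnorm(par$alpha_t, 0, 1, log = TRUE) +
    log(2) + dnorm(par$sigma_e, 0, 1, log = TRUE) +
    log(0.5) +
    log(2) + dnorm(par$beta_f[["repro.ad"]], 0, 1, log = TRUE) +
    sum(dnorm(par$beta_f[c("repro.lamb", "twin.ad")], 0, 1, log = TRUE)) +
    yearp
  expect_equal(lp, oracle, tolerance = 1e-10)
  # support guards return -Inf rather than raising
  bad <- par; bad$sigma_e <- -0.1
  expect_identical(log_prior(bad, spec), -Inf)
  bad2 <- par; bad2$theta[1] <- spec$theta_range[2] + 1
  expect_identical(log_prior(bad2, spec), -Inf)
  bad3 <- par; bad3$rho_ef <- 1.2
  expect_identical(log_prior(bad3, spec), -Inf)
  bad4 <- par; bad4$beta_f["repro.ad"] <- -0.5
  expect_identical(log_prior(bad4, spec), -Inf)
})

test_that("log posterior recomposes and propagates -Inf", {
  set.seed(13)
  pan <- random_panel(6)
  spec <- model_spec(pan, "baseline_2axis")
  par <- random_params(theta_range = spec$theta_range, n_years = 6)
  expect_equal(log_posterior(pan, par, spec),
               log_likelihood(pan, par, spec) + log_prior(par, spec),
               tolerance = 1e-12)
  bad <- par; bad$sigma_e <- -1
  expect_identical(log_posterior(pan, bad, spec), -Inf)
})

test_that("climate variants with null coefficients nest the baseline", {
  set.seed(23)
  scn <- truth_scenario(n_years = 8, params = soay_truth(climate = "flm"),
                        seed = 31)
  ds <- simulate_dataset(scn)
  spec_b <- model_spec(ds$panel, "baseline_2axis")
  spec_f <- model_spec(ds$panel, "flm_climate", climate = ds$climate)
  par <- random_params(theta_range = spec_b$theta_range, n_years = 8)
  par_f <- par; par_f$gamma <- rep(0, 8)
  expect_identical(log_likelihood(ds$panel, par, spec_b),
                   log_likelihood(ds$panel, par_f, spec_f))
  # the posterior differs exactly by the prior mass of the zero block
  expect_equal(log_posterior(ds$panel, par_f, spec_f) -
                 log_posterior(ds$panel, par, spec_b),
               8 * dnorm(0, 0, 1, log = TRUE), tolerance = 1e-10)
  spec_s <- model_spec(ds$panel, "scalar_climate", climate = rnorm(8))
  par_s <- par; par_s$beta_m <- 0
  expect_identical(log_likelihood(ds$panel, par, spec_b),
                   log_likelihood(ds$panel, par_s, spec_s))
})

test_that("increasing the axis decreases rates with positive loadings", {
  set.seed(29)
  p <- random_params()
  p$beta_e[] <- abs(p$beta_e)
  h <- 1e-6
  for (nm in sub11$name) {
    e0 <- if (sub11$thresholded[sub11$name == nm]) p$theta[[nm]] + 0.1 else 2.8
    d <- (linpred(nm, p, e0 + h, t = 0) - linpred(nm, p, e0 - h, t = 0)) / (2 * h)
    expect_lt(d, 0)
  }
})

test_that("compiled and reference log posteriors agree", {
  set.seed(41)
  for (r in 1:10) {
    pan <- random_panel(7)
    spec <- model_spec(pan, "baseline_2axis")
    par <- random_params(theta_range = spec$theta_range, n_years = 7)
    lay <- semflm:::param_layout(spec, pan$years)
    v <- semflm:::vec_to_internal(
      semflm:::flatten_params(par, spec, pan$years), spec, lay)
    m <- semflm:::build_model_list(pan, spec, lay)
    expect_equal(semflm:::cpp_log_posterior(v, m),
                 log_posterior(pan, par, spec), tolerance = 1e-8)
  }
})
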