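fake_elpd <- function(elpd, years = 2001:2005) {
  structure(list(elpd_hat = elpd, years = years), class = "elpd_result")
}

test_that("model comparison is the stated deviance-scale arithmetic", {
  expect_equal(compare_models(fake_elpd(-10), fake_elpd(-10)), 0)
  expect_equal(compare_models(fake_elpd(-10), fake_elpd(-12)), -4)
  a <- fake_elpd(-8.3); b <- fake_elpd(-11.7)
  expect_equal(compare_models(a, b), -compare_models(b, a))
  expect_error(compare_models(fake_elpd(-1, 2001:2005),
                              fake_elpd(-1, 2001:2006)), "incomparable")
})

test_that("a certain-likelihood cross-validation gives elpd zero", {
  pan <- toy_panel(c(0, 0, 0), c(0, 0, 0))
  spec <- intercept_only_spec(pan)
  cfg <- mcmc_config(n_chains = 2, n_iter = 500, n_burnin = 200, thin = 5,
                     seed = 2)
  res <- loyo_elpd(pan, spec, cfg, M = 1, S = 1)
  expect_equal(res$per_year_lpd, rep(0, 3))
  expect_equal(res$elpd_hat, 0)
  expect_equal(res$elpd_hat, sum(res$per_year_lpd))
})

test_that("Bayesian R2 is the stated variance ratio", {
  panel <- list(density = c(0, sqrt(6)), t = c(-0.5, 0.5),
                years = 2001:2002)                      # Var(density) = 3
  draws <- matrix(c(0, 1), 1, 2,
                  dimnames = list(NULL, c("alpha_t", "sigma_e")))
  post <- structure(list(draws = draws), class = "semflm_posterior")
  r2 <- bayes_r2(post, panel, list(climate_type = 0L))
  expect_equal(r2$median, 0.75)
  # constant fixed part is an error, not R2 = 0
  panel0 <- list(density = c(2, 2), t = c(-0.5, 0.5), years = 2001:2002)
  expect_error(bayes_r2(post, panel0, list(climate_type = 0L)), "undefined R2")
  # sigma -> 0 drives R2 -> 1
  draws1 <- matrix(c(0, 1e-8), 1, 2,
                   dimnames = list(NULL, c("alpha_t", "sigma_e")))
  post1 <- structure(list(draws = draws1), class = "semflm_posterior")
  expect_equal(bayes_r2(post1, panel, list(climate_type = 0L))$median, 1,
               tolerance = 1e-10)
})

test_that("posterior predictive checks flag gross misfit and respect bounds", {
  fit <- cached_small_fit()
  post <- fit$post; panel <- fit$ds$panel; spec <- fit$spec
  ppc <- posterior_predictive_check(post, panel, spec, n_rep = 200, seed = 5)
  ok <- !is.na(ppc$cells$tail_prob)
  expect_true(all(ppc$cells$tail_prob[ok] >= 0 & ppc$cells$tail_prob[ok] <= 1))
  expect_true(all(is.na(ppc$cells$tail_prob[ppc$cells$trials == 0])))
  expect_equal(sum(ppc$summary$n_years_used),
               sum(panel$trials > 0))
  # gross misfit: observed zeros against a fitted rate near the truth
  broken <- panel
  broken$successes["surv.ad.F", ] <- 0L
  ppc2 <- posterior_predictive_check(post, broken, spec, n_rep = 200, seed = 5)
  s2 <- ppc2$summary
  expect_equal(s2$share_flagged[s2$submodel == "surv.ad.F"], 1)
  # tail probability is monotone in the observed count
  cells <- ppc$cells[ppc$cells$submodel == "surv.ad.F", ]
  r <- cells[1, ]
  for (obs in c(0L, r$trials %/% 2L, r$trials)) {
    p3 <- panel
    p3$successes["surv.ad.F", 1] <- obs
    ppc3 <- posterior_predictive_check(post, p3, spec, n_rep = 100, seed = 5)
    cells3 <- ppc3$cells
    val <- cells3$tail_prob[cells3$submodel == "surv.ad.F" &
                              cells3$year == panel$years[1]]
    if (obs == 0L) expect_gt(val, 0.9) else if (obs == r$trials)
      expect_lt(val, 0.1)
  }
})

test_that("observed-vs-predicted correlations are high under the true model", {
  fit <- cached_small_fit()
  ovp <- obs_vs_pred(fit$post, fit$ds$panel, fit$spec)
  expect_equal(nrow(ovp), 11)
  surv <- ovp$correlation[grepl("^surv", ovp$submodel)]
  expect_true(all(surv > 0.7))
  # years with zero trials are excluded from the correlation
  expect_true(all(ovp$n_years <= length(fit$ds$panel$years)))
})

test_that("degenerate observed-vs-predicted cases are reported as NA", {
  fit <- cached_small_fit()
  pan <- fit$ds$panel
  pan$successes["surv.ad.F", ] <- pan$trials["surv.ad.F", ]  # constant obs
  ovp <- obs_vs_pred(fit$post, pan, fit$spec)
  expect_true(is.na(ovp$correlation[ovp$submodel == "surv.ad.F"]))
})

test_that("second-axis screening matches known structure", {
  fit <- cached_small_fit()
  post <- fit$post
  ef_med <- apply(post$draws[, grep("^eps_f\\.", colnames(post$draws))], 2,
                  median)
  scr <- axis_covariate_screen(post, list(self = ef_med,
                                          density = fit$ds$panel$density,
                                          flat = rep(1, length(ef_med))))
  expect_gt(scr$median[scr$covariate == "self"], 0.8)
  expect_true(is.na(scr$median[scr$covariate == "flat"]))
  expect_error(axis_covariate_screen(post, list(short = 1:3)), "length")
})

test_that("replicate simulation preserves trials and determinism", {
  fit <- cached_small_fit()
  r1 <- simulate_replicate(fit$post, fit$ds$panel, fit$spec, draw = 10,
                           seed = 4)
  r2 <- simulate_replicate(fit$post, fit$ds$panel, fit$spec, draw = 10,
                           seed = 4)
  expect_identical(r1$successes, r2$successes)
  expect_identical(r1$trials, fit$ds$panel$trials)
  expect_true(all(r1$successes <= r1$trials))
})
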