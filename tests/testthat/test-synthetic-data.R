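test_that("the generator is bit-identical given seed and scenario", {
  scn <- truth_scenario(n_years = 6, params = soay_truth(climate = "flm"),
                        seed = 5)
  a <- simulate_dataset(scn)
  b <- simulate_dataset(scn)
  expect_identical(a$panel, b$panel)
  expect_identical(a$density, b$density)
  expect_identical(a$daily, b$daily)
  expect_identical(a$axes, b$axes)
  c <- simulate_dataset(truth_scenario(n_years = 6,
                                       params = soay_truth(climate = "flm"),
                                       seed = 6))
  expect_false(identical(a$panel$successes, c$panel$successes))
})

test_that("density series honours its stated moments and guards", {
  scn0 <- truth_scenario(density_mean_log10 = 3, density_sd_log10 = 0,
                         n_years = 5)
  d0 <- simulate_density(scn0)
  expect_equal(d0$log10_count, rep(3, 5))
  expect_equal(d0$count, rep(1000L, 5))  # log10 identity
  expect_error(simulate_density(truth_scenario(density_mean_log10 = 1.2,
                                               density_sd_log10 = 0)),
               "below 30")
  # Monte-Carlo check of the generator mean
  means <- vapply(1:400, function(r)
    mean(simulate_density(truth_scenario(n_years = 10, seed = r))$log10_count),
    numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 2.78), 3 * se)
})

test_that("daily climate covers the span with the stated structure", {
  base <- climate_scenario(seasonal_amplitude = 0, daily_noise_sd = 0,
                           yearly_anomaly_sd = 0, missing_fraction = 0)
  scn <- truth_scenario(n_years = 3, start_year = 2002, climate = base)
  s <- simulate_climate_daily(scn)
  expect_equal(min(s$date), as.Date("2001-01-01"))
  expect_equal(max(s$date), as.Date("2004-07-31"))
  expect_true(all(s$value == 0))           # all-zero variance -> constant
  expect_false(anyNA(s$value))             # missing_fraction 0
  scn2 <- truth_scenario(n_years = 3, climate = climate_scenario(
    missing_fraction = 0.3))
  s2 <- simulate_climate_daily(scn2)
  expect_gt(mean(is.na(s2$value)), 0.2)
  expect_lt(mean(is.na(s2$value)), 0.4)
  expect_error(climate_scenario(missing_fraction = 0.6), "0.5")
  expect_error(climate_scenario(daily_noise_sd = -1), "non-negative")
})

test_that("pure seasonality aggregates to windows but centers to near zero", {
  scn <- truth_scenario(n_years = 3, start_year = 2002,
                        climate = climate_scenario(seasonal_amplitude = 5,
                                                   daily_noise_sd = 0,
                                                   yearly_anomaly_sd = 0,
                                                   missing_fraction = 0))
  s <- simulate_climate_daily(scn)
  m <- aggregate_windows(s, 2002:2004, "fortnight")
  expect_gt(sd(m$values[1, ]), 1)    # seasonality across windows
  cm <- center_windows(m)
  # residual anomalies only from the one-day leap shift, tiny vs amplitude
  expect_lt(max(abs(cm$values)), 0.1)
})

test_that("axes reduce to density in the degenerate case", {
  par <- soay_truth()
  par$sigma_e <- 0
  par$alpha_t <- 0
  scn <- truth_scenario(n_years = 5, params = par, seed = 2)
  den <- simulate_density(scn)
  ax <- simulate_axes(scn, den)
  expect_equal(ax$e, den$log10_count)
  expect_equal(ax$eps_e, rep(0, 5))
})

test_that("year-effect pairs follow the stated bivariate law", {
  par <- soay_truth()
  par$sigma_e <- 1
  par$rho_ef <- 0
  scn <- truth_scenario(n_years = 1e5, params = par, density_sd_log10 = 0,
                        seed = 7)
  den <- data.frame(year = seq_len(1e5), log10_count = rep(2.78, 1e5),
                    count = rep(603L, 1e5))
  ax <- simulate_axes(scn, den)
  expect_lt(abs(cor(ax$eps_e, ax$eps_f)), 0.01)
  expect_equal(sd(ax$eps_e), 1, tolerance = 0.02)
  expect_equal(sd(ax$eps_f), 1, tolerance = 0.02)
  par$rho_ef <- 0.6
  scn2 <- truth_scenario(n_years = 1e5, params = par, density_sd_log10 = 0,
                         seed = 7)
  ax2 <- simulate_axes(scn2, den)
  expect_equal(cor(ax2$eps_e, ax2$eps_f), 0.6, tolerance = 0.02)
})

test_that("a null lag function leaves the axis untouched", {
  par <- soay_truth(climate = "flm")
  par$gamma <- rep(0, 8)
  scn <- truth_scenario(n_years = 6, params = par, seed = 3)
  ds <- simulate_dataset(scn)
  scn0 <- truth_scenario(n_years = 6, params = soay_truth(), seed = 3)
  den0 <- simulate_density(scn0)
  ax0 <- simulate_axes(scn0, den0)
  expect_equal(ds$axes$e, ax0$e)
})

test_that("axes with and without climate differ only by the climate term", {
  scn <- truth_scenario(n_years = 8, params = soay_truth(climate = "flm"),
                        seed = 9)
  den <- simulate_density(scn)
  daily <- simulate_climate_daily(scn)
  cm <- center_windows(aggregate_windows(interpolate_missing(daily),
                                         semflm:::scenario_years(scn),
                                         "fortnight"))
  with_c <- simulate_axes(scn, den, cm)
  without <- simulate_axes(scn, den)
  expect_equal(with_c$e + with_c$climate_contrib, without$e, tolerance = 1e-12)
  expect_identical(with_c$eps_e, without$eps_e)
})

test_that("panel trials follow class sizes and fecundity bookkeeping", {
  scn <- truth_scenario(n_years = 10, seed = 13)
  den <- simulate_density(scn)
  ax <- simulate_axes(scn, den)
  pan <- simulate_panel(scn, ax, den)
  expect_equal(unname(pan$trials["surv.lamb.F", ]),
               as.integer(round(den$count / 6)))
  expect_equal(unname(pan$trials["repro.lamb", ]),
               unname(pan$successes["surv.lamb.F", ]))
  expect_equal(unname(pan$trials["twin.yrl", ]),
               unname(pan$successes["repro.lamb", ]))
  expect_equal(unname(pan$trials["twin.ad", ]),
               unname(pan$successes["repro.yrl", ] +
                        pan$successes["repro.ad", ]))
  expect_true(all(pan$successes <= pan$trials))
})

test_that("a certain event yields all successes; rare events yield zero-trial cells", {
  par <- soay_truth()
  par$beta0[] <- 40
  par$beta_e[] <- 0
  par$beta_f[] <- 0
  scn <- truth_scenario(n_years = 5, params = par, seed = 4)
  den <- simulate_density(scn)
  ax <- simulate_axes(scn, den)
  pan <- simulate_panel(scn, ax, den)
  expect_true(all(pan$successes == pan$trials))
  # suppress lamb reproduction -> yearling twinning gets zero-trial years
  par2 <- soay_truth()
  par2$beta0["repro.lamb"] <- -6 + par2$beta_e[["repro.lamb"]] * 2.78
  scn2 <- truth_scenario(n_years = 15, params = par2, seed = 8)
  ds2 <- simulate_dataset(scn2)
  expect_gt(sum(ds2$panel$trials["twin.yrl", ] == 0), 0)
  expect_true(all(ds2$panel$successes["twin.yrl",
                                      ds2$panel$trials["twin.yrl", ] == 0] == 0))
})

test_that("simulated frequencies agree with the binomial law", {
  par <- soay_truth()
  scn <- truth_scenario(n_years = 3, params = par, density_sd_log10 = 0, seed = 1)
  den <- simulate_density(scn)
  ax <- simulate_axes(scn, den)
  # known probability for one cell
  pr <- plogis(linpred("surv.ad.F", par, ax$e[2], ax$t[2]))
  ks <- vapply(1:600, function(r) {
    s2 <- scn; s2$seed <- 2000L + r
    simulate_panel(s2, ax, den)$successes["surv.ad.F", 2]
  }, numeric(1))
  n <- round(den$count[2] / 6)
  se <- sqrt(pr * (1 - pr) / (n * 600))
  expect_lt(abs(mean(ks) / n - pr), 3 * se)
})

test_that("large panels reproduce the piecewise threshold shape", {
  par <- soay_truth()
  shift <- 5.2 - 2.78
  nt <- !soay_submodels()$thresholded
  par$beta0[nt] <- par$beta0[nt] + par$beta_e[nt] * shift
  par$theta <- par$theta + shift
  par$alpha_t <- 0
  scn <- truth_scenario(n_years = 30, params = par, density_mean_log10 = 5.2,
                        density_sd_log10 = 0.08, seed = 19)
  den <- simulate_density(scn)
  ax <- simulate_axes(scn, den)
  pan <- simulate_panel(scn, ax, den)
  expect_gt(min(pan$trials["surv.ad.F", ]), 1e4)
  nm <- "surv.ad.F"; th <- par$theta[[nm]]
  prop <- pan$successes[nm, ] / pan$trials[nm, ]
  below <- ax$e < th
  expect_gt(sum(below), 4); expect_gt(sum(!below), 4)
  # flat below the threshold, declining above (1% level)
  fit_b <- summary(lm(qlogis(prop[below]) ~ ax$e[below]))$coefficients
  expect_gt(fit_b[2, 4], 0.01)
  fit_a <- summary(lm(qlogis(prop[!below]) ~ ax$e[!below]))$coefficients
  expect_lt(fit_a[2, 4], 0.01)
  expect_lt(fit_a[2, 1], 0)
})
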