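# Ground-truth synthetic data generator. Every simulate_* function is
# deterministic given scenario$seed (a stage-specific offset keeps the
# stages' streams distinct); the caller's RNG state is restored on exit.

with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Climate scenario for the daily weather generator
#'
#' @param seasonal_amplitude Amplitude of the within-year sinusoid.
#' @param daily_noise_sd SD of day-to-day noise.
#' @param yearly_anomaly_sd SD of the shared anomaly drawn once per
#'   calendar fortnight (this is the interannual signal the FLM can pick
#'   up after aggregation and centering).
#' @param missing_fraction Fraction of days set to missing at random
#'   (must be < 0.5).
#' @param variable_name Label for the simulated variable.
#' @return An object of class `"climate_scenario"`.
#' @export
climate_scenario <- function(seasonal_amplitude = 5, daily_noise_sd = 1.5,
                             yearly_anomaly_sd = 2, missing_fraction = 0.02,
                             variable_name = "precip") {
  if (seasonal_amplitude < 0 || daily_noise_sd < 0 || yearly_anomaly_sd < 0)
    stop("climate scenario amplitudes/SDs must be non-negative")
  if (missing_fraction < 0 || missing_fraction >= 0.5)
    stop("missing_fraction must be in [0, 0.5)")
  structure(list(seasonal_amplitude = seasonal_amplitude,
                 daily_noise_sd = daily_noise_sd,
                 yearly_anomaly_sd = yearly_anomaly_sd,
                 missing_fraction = missing_fraction,
                 variable_name = variable_name),
            class = "climate_scenario")
}

#' Ground-truth scenario for the synthetic study system
#'
#' Bundles everything the generator needs: the submodel design, true
#' parameters, the density regime (mean/SD of log10 August counts and the
#' AR(1) mean-reversion coefficient), the fraction of the population in
#' each age-sex class (sets survival trial counts; fecundity trials
#' derive from survival and reproduction outcomes), and the daily-weather
#' scenario. Defaults emulate a ~600-animal population observed for 30
#' years, giving roughly 100 survival trials per class per year.
#'
#' @param n_years Number of study years (>= 3).
#' @param start_year First calendar study year.
#' @param submodels Submodel table.
#' @param params True parameters (see [soay_truth()]).
#' @param density_mean_log10,density_sd_log10 Mean and stationary SD of
#'   the log10 density series.
#' @param density_ar1 AR(1) coefficient of the mean-reverting log10
#'   random walk.
#' @param class_fractions Named fractions of the August population in the
#'   six age-sex classes (each in (0,1), summing to at most 1).
#' @param climate A `"climate_scenario"`.
#' @param seed Integer seed.
#' @return An object of class `"truth_scenario"`.
#' @export
truth_scenario <- function(n_years = 30, start_year = 1985,
                           submodels = soay_submodels(),
                           params = soay_truth(submodels),
                           density_mean_log10 = 2.78,
                           density_sd_log10 = 0.12,
                           density_ar1 = 0.6,
                           class_fractions = c(lamb.F = 1/6, lamb.M = 1/6,
                                               yrl.F = 1/6, yrl.M = 1/6,
                                               ad.F = 1/6, ad.M = 1/6),
                           climate = climate_scenario(),
                           seed = 1) {
  if (n_years < 3) stop("n_years must be at least 3")
  if (density_sd_log10 < 0) stop("density_sd_log10 must be non-negative")
  if (any(class_fractions <= 0) || any(class_fractions >= 1))
    stop("class fractions must lie in (0, 1)")
  if (sum(class_fractions) > 1 + 1e-9)
    stop("class fractions must sum to at most 1")
  validate_params(params, submodels)
  structure(list(n_years = as.integer(n_years),
                 start_year = as.integer(start_year),
                 submodels = submodels, params = params,
                 density_mean_log10 = density_mean_log10,
                 density_sd_log10 = density_sd_log10,
                 density_ar1 = density_ar1,
                 class_fractions = class_fractions,
                 climate = climate, seed = as.integer(seed)),
            class = "truth_scenario")
}

scenario_years <- function(scenario)
  scenario$start_year + seq_len(scenario$n_years) - 1L

#' Simulate the density series
#'
#' Mean-reverting AR(1) random walk on the log10 scale with the stated
#' stationary mean and SD. Density is exogenous: the inferential model
#' conditions on it rather than modelling feedback from survival.
#'
#' @param scenario A `"truth_scenario"`.
#' @return Data frame with columns `year`, `log10_count`, `count`
#'   (`count = round(10^log10_count)`).
#' @export
simulate_density <- function(scenario) {
  with_seed(scenario$seed + 1L, {
    T_ <- scenario$n_years
    mu <- scenario$density_mean_log10
    s <- scenario$density_sd_log10
    phi <- scenario$density_ar1
    D <- numeric(T_)
    if (s == 0) {
      D[] <- mu
    } else {
      innov_sd <- s * sqrt(1 - phi^2)
      D[1] <- mu + rnorm(1, 0, s)
      for (t in 2:T_) D[t] <- mu + phi * (D[t - 1] - mu) + rnorm(1, 0, innov_sd)
    }
    count <- round(10^D)
    if (any(count < 30))
      stop("invalid scenario: simulated population below 30 animals (trial counts would degenerate)")
    data.frame(year = scenario_years(scenario), log10_count = D,
               count = count)
  })
}

#' Simulate a daily weather series
#'
#' One value per calendar day from 1 January of the year before the first
#' study year through 31 July of the last study year: a seasonal sinusoid
#' plus a shared anomaly drawn once per calendar fortnight (the
#' interannual signal) plus daily noise; a fraction of days is then set
#' missing at random.
#'
#' @param scenario A `"truth_scenario"`.
#' @return A `"daily_climate"` series (missing days are `NA`).
#' @export
simulate_climate_daily <- function(scenario) {
  cs <- scenario$climate
  with_seed(scenario$seed + 2L, {
    years <- scenario_years(scenario)
    d0 <- as.Date(sprintf("%d-01-01", years[1] - 1L))
    d1 <- as.Date(sprintf("%d-07-31", years[scenario$n_years]))
    dates <- seq(d0, d1, by = "day")
    n <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    seasonal <- cs$seasonal_amplitude * sin(2 * pi * (doy - 105) / 365.25)
    fortnight <- as.integer(dates - d0) %/% 14L
    anom <- rnorm(max(fortnight) + 1L, 0, cs$yearly_anomaly_sd)
    v <- seasonal + anom[fortnight + 1L] + rnorm(n, 0, cs$daily_noise_sd)
    if (cs$missing_fraction > 0)
      v[runif(n) < cs$missing_fraction] <- NA_real_
    daily_climate(dates, v, cs$variable_name)
  })
}

#' Simulate the latent environmental axes
#'
#' Draws the year-effect pairs `(eps_e, eps_f)` from their bivariate
#' normal law (SDs `sigma_e` and 1, correlation `rho_ef`) and computes the
#' first axis `e(t) = D_t - climate - alpha_t t - eps_e`. The climate
#' contribution is `sum_w f_c(w) C_tw` when a centered climate matrix is
#' supplied and the truth carries FLM coefficients, `beta_m M_t` when a
#' scalar covariate is supplied and the truth carries `beta_m`, else zero.
#'
#' @param scenario A `"truth_scenario"`.
#' @param density Data frame from [simulate_density()].
#' @param climate `NULL`, a centered `"climate_matrix"`, or a per-year
#'   numeric covariate.
#' @return An `"axis_state"`: list with `e`, `eps_e`, `eps_f`,
#'   `climate_contrib` and `t` (centered year index).
#' @export
simulate_axes <- function(scenario, density, climate = NULL) {
  p <- scenario$params
  validate_params(p, scenario$submodels)
  T_ <- scenario$n_years
  if (nrow(density) != T_) stop("density length must equal n_years")
  tc <- seq_len(T_) - mean(seq_len(T_))
  cc <- rep(0, T_)
  if (!is.null(climate)) {
    if (inherits(climate, "climate_matrix")) {
      if (is.null(p$gamma))
        stop("scenario params carry no FLM coefficients for a climate matrix")
      term <- build_cr_basis(ncol(climate$values), length(p$gamma))
      cc <- flm_contribution(term, climate, p$gamma)
    } else {
      if (is.null(p$beta_m))
        stop("scenario params carry no scalar climate slope")
      cc <- p$beta_m * as.numeric(climate)
    }
  }
  with_seed(scenario$seed + 3L, {
    z1 <- rnorm(T_); z2 <- rnorm(T_)
    eps_e <- p$sigma_e * z1
    eps_f <- p$rho_ef * z1 + sqrt(1 - p$rho_ef^2) * z2
    e <- axis_value(density$log10_count, tc, p$alpha_t, cc, eps_e)
    structure(list(e = e, eps_e = eps_e, eps_f = eps_f,
                   climate_contrib = cc, t = tc),
              class = "axis_state")
  })
}

#' Simulate the demographic panel
#'
#' Sets survival trial counts from the August population size and the
#' class fractions, computes each submodel's success probability from the
#' true linear predictors, and draws binomial successes. Fecundity trials
#' follow the demographic bookkeeping: reproduction trials are the
#' surviving ewes of the class; yearling twinning trials are the ewes
#' that reproduced as lambs (they lamb as yearlings); adult twinning
#' trials are the yearling and adult reproducers. Zero-trial cells are
#' recorded as trials = 0, successes = 0.
#'
#' @param scenario A `"truth_scenario"`.
#' @param axes An `"axis_state"` from [simulate_axes()].
#' @param density Data frame from [simulate_density()].
#' @return A `"demographic_panel"`.
#' @export
simulate_panel <- function(scenario, axes, density) {
  sub <- scenario$submodels
  p <- scenario$params
  T_ <- scenario$n_years
  if (length(axes$e) != T_ || nrow(density) != T_)
    stop("axes and density must match n_years")
  with_seed(scenario$seed + 4L, {
    N <- density$count
    frac <- scenario$class_fractions
    class_of <- paste(sub$age_class, sub$sex, sep = ".")
    class_key <- c(lamb.F = "lamb.F", lamb.M = "lamb.M",
                   yearling.F = "yrl.F", yearling.M = "yrl.M",
                   adult.F = "ad.F", adult.M = "ad.M")
    trials <- successes <- matrix(0L, nrow(sub), T_,
                                  dimnames = list(sub$name, density$year))
    prob <- matrix(NA_real_, nrow(sub), T_, dimnames = dimnames(trials))
    for (i in seq_len(nrow(sub))) {
      ef <- if (sub$second_axis[i]) axes$eps_f else NULL
      prob[i, ] <- plogis(linpred(sub[i, ], p, axes$e, axes$t, eps_f = ef,
                                  submodels = sub))
    }
    draw_row <- function(name, n) {
      n <- as.integer(pmax(n, 0))
      trials[name, ] <<- n
      k <- integer(T_)
      pos <- n > 0
      k[pos] <- rbinom(sum(pos), n[pos], prob[name, pos])
      successes[name, ] <<- k
      k
    }
    surv_k <- list()
    for (i in which(sub$process == "survival")) {
      cls <- class_key[[class_of[i]]]
      surv_k[[sub$name[i]]] <- draw_row(sub$name[i], round(N * frac[[cls]]))
    }
    repro_k <- list()
    for (i in which(sub$process == "reproduction")) {
      nm <- sub$name[i]
      src <- switch(sub$age_class[i], lamb = "surv.lamb.F",
                    yearling = "surv.yrl.F", adult = "surv.ad.F")
      repro_k[[nm]] <- draw_row(nm, surv_k[[src]])
    }
    for (i in which(sub$process == "twinning")) {
      nm <- sub$name[i]
      n <- if (sub$age_class[i] == "yearling") repro_k[["repro.lamb"]]
           else repro_k[["repro.yrl"]] + repro_k[["repro.ad"]]
      draw_row(nm, n)
    }
    demographic_panel(density$year, density$log10_count, trials, successes,
                      sub)
  })
}

#' Simulate a complete study data set
#'
#' Convenience wrapper running the full generator pipeline: density,
#' daily weather, window aggregation and centering (when the truth
#' carries climate coefficients), axes, and the demographic panel.
#'
#' @param scenario A `"truth_scenario"`.
#' @param scheme Lag-window scheme for the FLM climate matrix.
#' @return List with `panel`, `density`, `daily` (daily series or
#'   `NULL`), `climate` (centered `"climate_matrix"` or `NULL`), `axes`,
#'   `truth` (the scenario's parameters) and `scenario`.
#' @export
simulate_dataset <- function(scenario, scheme = c("fortnight", "month")) {
  scheme <- match.arg(scheme)
  density <- simulate_density(scenario)
  daily <- NULL; cmat <- NULL
  if (!is.null(scenario$params$gamma)) {
    daily <- simulate_climate_daily(scenario)
    cmat <- center_windows(aggregate_windows(interpolate_missing(daily),
                                             scenario_years(scenario),
                                             scheme))
    axes <- simulate_axes(scenario, density, cmat)
  } else if (!is.null(scenario$params$beta_m)) {
    daily <- simulate_climate_daily(scenario)
    cov <- scalar_covariate(interpolate_missing(daily), "march_precip",
                            scenario_years(scenario))
    axes <- simulate_axes(scenario, density, cov$value)
    cmat <- cov
  } else {
    axes <- simulate_axes(scenario, density)
  }
  panel <- simulate_panel(scenario, axes, density)
  list(panel = panel, density = density, daily = daily, climate = cmat,
       axes = axes, truth = scenario$params, scenario = scenario)
}
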