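#' Construct a demographic panel
#'
#' Per-year, per-submodel binomial trial and success counts together with
#' the density series. The year covariate used throughout the models is
#' the centered integer index `t - mean(t)` (numerically stable and makes
#' intercepts refer to the mid-study year).
#'
#' @param years Integer year labels (e.g. calendar years).
#' @param density Per-year density `D_t` (log10 August population count).
#' @param trials,successes Submodel x year integer matrices with rownames
#'   matching `submodels$name` and one column per year. Zero-trial cells
#'   are legal and contribute zero likelihood.
#' @param submodels Submodel table (see [soay_submodels()]).
#' @return An object of class `"demographic_panel"`.
#' @export
demographic_panel <- function(years, density, trials, successes,
                              submodels = soay_submodels()) {
  validate_submodels(submodels)
  years <- as.integer(years)
  T_ <- length(years)
  stopifnot(length(density) == T_)
  if (!all(is.finite(density))) stop("density must be finite")
  trials <- as.matrix(trials); successes <- as.matrix(successes)
  if (!identical(dim(trials), dim(successes)))
    stop("trials and successes must have identical dimensions")
  if (nrow(trials) != nrow(submodels) || ncol(trials) != T_)
    stop("trials must be n_submodels x n_years")
  if (is.null(rownames(trials))) rownames(trials) <- submodels$name
  if (is.null(rownames(successes))) rownames(successes) <- submodels$name
  if (any(successes < 0) || any(trials < 0) || any(successes > trials))
    stop("data error: need 0 <= successes <= trials")
  colnames(trials) <- colnames(successes) <- years
  structure(list(
    years = years,
    t = seq_len(T_) - mean(seq_len(T_)),
    density = as.numeric(density),
    trials = trials, successes = successes,
    submodels = submodels
  ), class = "demographic_panel")
}

#' Keep a subset of years of a panel
#'
#' Subsets the demographic outcomes and density while *retaining* the
#' centered year index values of the full panel, so that cross-validation
#' refits use the same covariate scale as the full fit.
#'
#' @param panel A `"demographic_panel"`.
#' @param keep Logical or integer index over years.
#' @return A `"demographic_panel"` restricted to the selected years.
#' @export
subset_years <- function(panel, keep) {
  out <- panel
  out$years <- panel$years[keep]
  out$t <- panel$t[keep]
  out$density <- panel$density[keep]
  out$trials <- panel$trials[, keep, drop = FALSE]
  out$successes <- panel$successes[, keep, drop = FALSE]
  out
}

#' Default weakly informative priors
#'
#' Priors are weakly informative on the logit scale and proper. The
#' intercept prior `N(0, 1.5^2)` applies to each submodel's rate-logit at
#' average observed density: directly for thresholded submodels (whose
#' intercept is the below-threshold rate) and to the centered intercept
#' `beta0 - beta_e * mean(e)` for the others, because with density
#' entering un-standardized on the log10 scale the raw intercept is an
#' extrapolation to axis value zero and can legitimately reach into the
#' teens. Axis loadings get `beta_e ~ N(0, 10^2)` (several logits per
#' log10-density unit are plausible); temporal trends, the axis trend,
#' scalar-climate slopes, second-axis loadings and FLM coefficients
#' `~ N(0, 1)`; `sigma_e ~ Half-Normal(1)`;
#' `rho_ef ~ Uniform(-1, 1)`; each threshold uniform over the central 90%
#' range of observed density. The second-axis loading of adult
#' reproduction is constrained positive (Half-Normal(1)) to fix the sign
#' of the second axis. Setting `beta0 = "flat_prob"` replaces the
#' intercept prior with a uniform prior on the success probability
#' (logistic density on the logit scale), used for conjugate checks.
#'
#' @param beta0 `"normal"` or `"flat_prob"`.
#' @param beta0_sd,slope_sd,beta_e_sd,gamma_sd,sigma_scale Prior scales.
#' @return A list of prior settings.
#' @export
default_priors <- function(beta0 = "normal", beta0_sd = 1.5, slope_sd = 1,
                           beta_e_sd = 10, gamma_sd = 1, sigma_scale = 1) {
  list(beta0 = match.arg(beta0, c("normal", "flat_prob")),
       beta0_sd = beta0_sd, slope_sd = slope_sd, beta_e_sd = beta_e_sd,
       gamma_sd = gamma_sd, sigma_scale = sigma_scale)
}

#' Construct a model specification
#'
#' Defines the model variant, climate terms, priors and any parameters
#' held fixed. The two-axis structure is used by every variant except
#' `baseline_1axis`; the climate variants build on the two-axis model.
#' Threshold prior bounds (central 90% range of observed density) are
#' computed here from the panel.
#'
#' @param panel A `"demographic_panel"` (supplies the submodel table,
#'   density range for threshold priors, and year labels for climate
#'   alignment).
#' @param variant One of `"baseline_2axis"`, `"baseline_1axis"`,
#'   `"scalar_climate"`, `"flm_climate"`.
#' @param climate For `"scalar_climate"`: a per-year numeric vector (or
#'   data frame from [scalar_covariate()], standardized values). For
#'   `"flm_climate"`: a centered `"climate_matrix"`. Ignored otherwise.
#' @param n_knots Number of spline knots for the FLM term.
#' @param priors Prior settings from [default_priors()].
#' @param fixed Named numeric vector of parameters to hold fixed at the
#'   given values (excluded from sampling); names as in the flattened
#'   parameter vector (see [param_names()]).
#' @return An object of class `"semflm_spec"`.
#' @export
model_spec <- function(panel,
                       variant = c("baseline_2axis", "baseline_1axis",
                                   "scalar_climate", "flm_climate"),
                       climate = NULL, n_knots = 8,
                       priors = default_priors(), fixed = NULL) {
  variant <- match.arg(variant)
  sub <- panel$submodels
  two_axis <- variant != "baseline_1axis"
  Mcov <- NULL; term <- NULL; Cmat <- NULL
  if (variant == "scalar_climate") {
    if (is.null(climate)) stop("scalar_climate requires a per-year covariate")
    Mcov <- if (is.data.frame(climate)) climate$value else as.numeric(climate)
    if (length(Mcov) != length(panel$years))
      stop("scalar covariate length does not match panel years")
  } else if (variant == "flm_climate") {
    if (!inherits(climate, "climate_matrix"))
      stop("flm_climate requires a climate_matrix")
    if (!isTRUE(climate$centered))
      stop("climate matrix must be centered (see center_windows)")
    if (!identical(as.integer(climate$years), as.integer(panel$years)))
      stop("climate matrix years do not match panel years")
    Cmat <- climate$values
    term <- build_cr_basis(ncol(Cmat), n_knots)
    term$variable_name <- climate$variable_name
  } else if (!is.null(climate)) {
    stop("baseline variants carry no climate terms")
  }
  theta_range <- if (any(sub$thresholded))
    unname(quantile(panel$density, c(0.05, 0.95))) else NULL
  structure(list(
    variant = variant, submodels = sub, two_axis = two_axis,
    climate_type = switch(variant, scalar_climate = 1L, flm_climate = 2L, 0L),
    Mcov = Mcov, term = term, Cmat = Cmat,
    priors = priors, theta_range = theta_range,
    axis_center = mean(panel$density),
    fixed = fixed
  ), class = "semflm_spec")
}

#' First environmental axis value
#'
#' `e(t) = D_t - climate_contrib - alpha_t * t - eps_e`, the latent axis
#' that all vital rates respond to: density, minus any climate
#' contribution, minus the axis temporal trend, minus the residual year
#' effect. Vectorized over years.
#'
#' @param D Density (log10 count).
#' @param t Centered year index.
#' @param alpha_t Axis trend slope.
#' @param climate_contrib Climate contribution (0 for baseline;
#'   `beta_m * M_t` for scalar; `sum_w f_c(w) C_tw` for FLM terms;
#'   additive across terms).
#' @param eps_e First-axis year effect.
#' @return Numeric axis value(s).
#' @export
axis_value <- function(D, t, alpha_t, climate_contrib = 0, eps_e = 0) {
  D - climate_contrib - alpha_t * t - eps_e
}

#' Linear predictor of one vital-rate submodel
#'
#' Thresholded survival submodels are flat in the axis below the threshold
#' and decline linearly above it:
#' `eta = beta0 + beta_t * t` for `e < theta`, and
#' `eta = beta0 + beta_t * t - beta_e * (e - theta)` for `e >= theta`
#' (continuous at the threshold by construction). Non-thresholded
#' submodels use `eta = beta0 + beta_t * t - beta_e * e`, plus
#' `beta_f * eps_f` for submodels loading on the second axis. The success
#' probability is `plogis(eta)`.
#'
#' @param sub A single row of the submodel table (or a submodel name plus
#'   `submodels` to look it up).
#' @param params A `"semflm_params"` object.
#' @param e Axis value(s).
#' @param t Centered year index (same length as `e` or scalar).
#' @param eps_f Second-axis year effect; only legal for submodels with
#'   `second_axis = TRUE` (supplying a nonzero value elsewhere is a
#'   contract violation).
#' @param submodels Submodel table used when `sub` is given as a name.
#' @return Logit-scale linear predictor, vectorized like `e`.
#' @export
linpred <- function(sub, params, e, t, eps_f = NULL,
                    submodels = soay_submodels()) {
  if (is.character(sub)) sub <- submodels[submodels$name == sub, ]
  if (nrow(sub) != 1) stop("sub must identify exactly one submodel")
  nm <- sub$name
  if (!is.null(eps_f) && !sub$second_axis && any(eps_f != 0))
    stop("contract violation: eps_f supplied for submodel '", nm,
         "' which does not load on the second axis")
  base <- params$beta0[[nm]] + params$beta_t[[nm]] * t
  if (sub$thresholded) {
    th <- params$theta[[nm]]
    ifelse(e < th, base, base - params$beta_e[[nm]] * (e - th))
  } else {
    eta <- base - params$beta_e[[nm]] * e
    if (sub$second_axis && !is.null(eps_f))
      eta <- eta + params$beta_f[[nm]] * eps_f
    eta
  }
}

# Climate contribution vector for a spec + params (0 / scalar / FLM).
climate_contribution <- function(spec, params, n_years) {
  if (spec$climate_type == 1L) {
    if (is.null(params$beta_m)) stop("params lack beta_m for scalar_climate")
    params$beta_m * spec$Mcov
  } else if (spec$climate_type == 2L) {
    if (is.null(params$gamma)) stop("params lack gamma for flm_climate")
    flm_contribution(spec$term, spec$Cmat, params$gamma)
  } else {
    rep(0, n_years)
  }
}

# S x T matrix of linear predictors for a full panel.
eta_matrix <- function(panel, params, spec) {
  sub <- spec$submodels
  T_ <- length(panel$years)
  cc <- climate_contribution(spec, params, T_)
  e <- axis_value(panel$density, panel$t, params$alpha_t, cc, params$eps_e)
  eps_f <- if (spec$two_axis) params$eps_f else rep(0, T_)
  eta <- matrix(NA_real_, nrow(sub), T_,
                dimnames = list(sub$name, panel$years))
  for (i in seq_len(nrow(sub))) {
    eta[i, ] <- linpred(sub[i, ], params, e, panel$t,
                        eps_f = if (sub$second_axis[i]) eps_f else NULL)
  }
  eta
}

#' Binomial log-likelihood of a demographic panel
#'
#' Sum over years and submodels of the binomial log probability mass
#' (including the binomial coefficient, so downstream elpd values are
#' proper log predictive densities) of the observed successes given the
#' trials and the model probabilities. Cells with zero trials contribute
#' exactly zero.
#'
#' @param panel A `"demographic_panel"`.
#' @param params A `"semflm_params"` with year effects set.
#' @param spec A `"semflm_spec"`.
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(panel, params, spec) {
  eta <- eta_matrix(panel, params, spec)
  p <- plogis(eta)
  use <- panel$trials > 0
  sum(dbinom(panel$successes[use], panel$trials[use], p[use], log = TRUE))
}

#' Joint log prior density
#'
#' Sum of the log prior densities of all parameters (see
#' [default_priors()]) plus the log density of the year effects: under the
#' two-axis model the pairs `(eps_e_t, eps_f_t)` are bivariate normal with
#' zero mean, SDs `(sigma_e, 1)` and correlation `rho_ef`; under the
#' single-axis model `eps_e_t ~ N(0, sigma_e)`. Parameters outside the
#' prior support give `-Inf` (returned, not raised).
#'
#' @inheritParams log_likelihood
#' @return Scalar log prior density (possibly `-Inf`).
#' @export
log_prior <- function(params, spec) {
  pr <- spec$priors
  sub <- spec$submodels
  if (!is.finite(params$sigma_e) || params$sigma_e <= 0) return(-Inf)
  lp <- 0
  # the intercept prior refers to the rate-logit at average density
  ec <- if (is.null(spec$axis_center)) 0 else spec$axis_center
  b0c <- params$beta0
  nt <- !sub$thresholded
  b0c[nt] <- b0c[nt] - params$beta_e[nt] * ec
  lp <- lp + if (pr$beta0 == "flat_prob")
    sum(dlogis(b0c, log = TRUE))
  else sum(dnorm(b0c, 0, pr$beta0_sd, log = TRUE))
  lp <- lp + sum(dnorm(params$beta_t, 0, pr$slope_sd, log = TRUE))
  lp <- lp + sum(dnorm(params$beta_e, 0, pr$beta_e_sd, log = TRUE))
  if (any(sub$thresholded)) {
    rng <- spec$theta_range
    if (any(params$theta < rng[1] | params$theta > rng[2])) return(-Inf)
    lp <- lp - length(params$theta) * log(rng[2] - rng[1])
  }
  lp <- lp + dnorm(params$alpha_t, 0, pr$slope_sd, log = TRUE)
  # sigma_e ~ Half-Normal(sigma_scale)
  lp <- lp + log(2) + dnorm(params$sigma_e, 0, pr$sigma_scale, log = TRUE)
  if (spec$two_axis) {
    if (abs(params$rho_ef) >= 1) return(-Inf)
    lp <- lp + log(0.5)  # rho ~ Uniform(-1, 1)
    bf <- params$beta_f
    con <- names(bf) == "repro.ad"
    if (any(con)) {
      if (any(bf[con] <= 0)) return(-Inf)
      lp <- lp + sum(log(2) + dnorm(bf[con], 0, pr$slope_sd, log = TRUE))
    }
    lp <- lp + sum(dnorm(bf[!con], 0, pr$slope_sd, log = TRUE))
  }
  if (spec$climate_type == 1L)
    lp <- lp + dnorm(params$beta_m, 0, pr$slope_sd, log = TRUE)
  if (spec$climate_type == 2L)
    lp <- lp + sum(dnorm(params$gamma, 0, pr$gamma_sd, log = TRUE))
  # year effects
  if (spec$two_axis) {
    s <- params$sigma_e; r <- params$rho_ef
    q <- (params$eps_e^2 / s^2 - 2 * r * params$eps_e * params$eps_f / s +
            params$eps_f^2) / (1 - r^2)
    lp <- lp + sum(-log(2 * pi) - 0.5 * log(s^2 * (1 - r^2)) - 0.5 * q)
  } else {
    lp <- lp + sum(dnorm(params$eps_e, 0, params$sigma_e, log = TRUE))
  }
  lp
}

#' Joint log posterior density (up to a constant)
#'
#' `log_likelihood + log_prior`; `-Inf` from the prior propagates without
#' evaluating the likelihood.
#'
#' @inheritParams log_likelihood
#' @return Scalar log posterior density.
#' @export
log_posterior <- function(panel, params, spec) {
  lp <- log_prior(params, spec)
  if (!is.finite(lp)) return(-Inf)
  lp + log_likelihood(panel, params, spec)
}
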