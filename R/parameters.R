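#' Construct a vital-rate parameter set
#'
#' Container for every parameter of the SEM: per-submodel intercepts and
#' slopes, survival thresholds, axis decomposition coefficients, latent
#' year effects and (optionally) climate coefficients. The names of
#' `beta0`, `beta_t` and `beta_e` must match the submodel table; `theta` is
#' named by the thresholded submodels and `beta_f` by the submodels loading
#' on the second axis.
#'
#' @param submodels Submodel table (see [soay_submodels()]).
#' @param beta0,beta_t,beta_e Named numeric vectors, one entry per
#'   submodel: logit-scale intercepts, temporal-trend slopes and first-axis
#'   loadings.
#' @param theta Named numeric vector of thresholds for the thresholded
#'   survival submodels (on the scale of the environmental axis, i.e.
#'   log10 density units).
#' @param beta_f Named numeric vector of second-axis loadings (may be
#'   `NULL` for single-axis models).
#' @param alpha_t Temporal-trend slope of the first axis (log10 density
#'   units per year).
#' @param sigma_e Standard deviation of the first-axis year effects
#'   (> 0). The second-axis year effects have unit standard deviation by
#'   convention (see the methods vignette).
#' @param rho_ef Correlation between the first- and second-axis year
#'   effects, in (-1, 1).
#' @param beta_m Scalar-climate slope (reference models), or `NULL`.
#' @param gamma FLM basis coefficients (values of the lag-coefficient
#'   function at the knots), or `NULL`.
#' @param eps_e,eps_f Latent year effects (numeric vectors of length
#'   `n_years`; `eps_f` may be `NULL` for single-axis models).
#' @return An object of class `"semflm_params"`.
#' @export
vital_params <- function(submodels,
                         beta0, beta_t, beta_e,
                         theta = NULL, beta_f = NULL,
                         alpha_t = 0, sigma_e = 0.1, rho_ef = 0,
                         beta_m = NULL, gamma = NULL,
                         eps_e = NULL, eps_f = NULL) {
  validate_submodels(submodels)
  nm <- submodels$name
  as_named <- function(x, names_needed, what) {
    if (is.null(names(x))) {
      if (length(x) != length(names_needed))
        stop(what, " must have one entry per submodel")
      names(x) <- names_needed
    }
    if (!setequal(names(x), names_needed))
      stop(what, " names must match: ", paste(names_needed, collapse = ", "))
    x[names_needed]
  }
  p <- structure(list(
    beta0 = as_named(beta0, nm, "beta0"),
    beta_t = as_named(beta_t, nm, "beta_t"),
    beta_e = as_named(beta_e, nm, "beta_e"),
    theta = if (any(submodels$thresholded))
      as_named(theta, nm[submodels$thresholded], "theta") else NULL,
    beta_f = if (!is.null(beta_f))
      as_named(beta_f, nm[submodels$second_axis], "beta_f") else NULL,
    alpha_t = alpha_t, sigma_e = sigma_e, rho_ef = rho_ef,
    beta_m = beta_m, gamma = gamma,
    eps_e = eps_e, eps_f = eps_f
  ), class = "semflm_params")
  validate_params(p, submodels)
  p
}

#' Validate a parameter set against a submodel table
#'
#' Checks dimensional consistency and the hard support constraints
#' `sigma_e > 0` and `|rho_ef| < 1` (the year-effect covariance matrix must
#' be positive definite).
#'
#' @param params A `"semflm_params"` object.
#' @param submodels Submodel table the parameters refer to.
#' @return `params`, invisibly.
#' @export
validate_params <- function(params, submodels) {
  S <- nrow(submodels)
  stopifnot(length(params$beta0) == S, length(params$beta_t) == S,
            length(params$beta_e) == S)
  if (any(submodels$thresholded) &&
      length(params$theta) != sum(submodels$thresholded))
    stop("theta must have one entry per thresholded submodel")
  if (!is.null(params$beta_f) &&
      length(params$beta_f) != sum(submodels$second_axis))
    stop("beta_f must have one entry per second-axis submodel")
  # sigma_e = 0 is allowed as a degenerate generator case (year effects
  # identically zero); the model prior still requires sigma_e > 0
  if (!is.finite(params$sigma_e) || params$sigma_e < 0)
    stop("sigma_e must be non-negative")
  if (!is.finite(params$rho_ef) || abs(params$rho_ef) >= 1)
    stop("|rho_ef| must be < 1 (year-effect covariance not positive definite)")
  if (!is.null(params$eps_f) && !is.null(params$eps_e) &&
      length(params$eps_f) != length(params$eps_e))
    stop("eps_e and eps_f must have equal length")
  invisible(params)
}

#' Default ground-truth parameters for the synthetic study system
#'
#' A parameter set on the scale of the emulated sheep system: density is
#' log10 August population size (~2.78, i.e. about 600 animals), so axis
#' loadings are logits per log10-density unit. Thresholded survival
#' intercepts are the (high) below-threshold survival logits, with
#' thresholds ~0.3 SD below mean density so roughly a third of years fall
#' in the flat (resource-rich) regime. Non-thresholded intercepts are
#' extrapolations to axis value zero and therefore absorb
#' `beta_e * mean(e)`; at mean density they imply moderate male lamb
#' survival (~0.7), reproduction rates from ~0.25 (lambs) to ~0.9
#' (adults), rare yearling twinning (~0.03) and uncommon adult twinning
#' (~0.12). The axis trend `alpha_t` (0.015/yr) accumulates
#' to about 0.45 log10 units over 30 years, comparable to the long-term
#' density increase in the study population.
#'
#' @param submodels Submodel table.
#' @param climate `"none"`, `"flm"` (includes the two-lobe lag-coefficient
#'   truth as `gamma`), or `"scalar"` (includes `beta_m`).
#' @param n_windows,n_knots FLM dimensions used when `climate = "flm"`.
#' @return A `"semflm_params"` object (without year effects; those are
#'   drawn by [simulate_axes()]).
#' @export
soay_truth <- function(submodels = soay_submodels(),
                       climate = c("none", "flm", "scalar"),
                       n_windows = 42, n_knots = 8) {
  climate <- match.arg(climate)
  validate_submodels(submodels, canonical = TRUE)
  gamma <- NULL
  beta_m <- NULL
  if (climate == "flm") {
    term <- build_cr_basis(n_windows, n_knots)
    gamma <- default_lag_effect(term$knots)
  } else if (climate == "scalar") {
    beta_m <- 0.08
  }
  vital_params(
    submodels,
    beta0 = c(1.2, 9.2, 2.2, 1.8, 2.8, 2.0, 12.8, 8.1, 6.2, -0.7, 5.0),
    beta_t = rep(0, 11),
    beta_e = c(4.0, 3.0, 3.5, 4.0, 3.0, 4.5, 5.0, 2.5, 1.5, 1.0, 2.5),
    theta = c(2.70, 2.72, 2.74, 2.76, 2.72),
    beta_f = c(1.0, 0.8, 0.6),
    alpha_t = 0.015, sigma_e = 0.1, rho_ef = 0.3,
    beta_m = beta_m, gamma = gamma
  )
}

#' Two-lobe default lag-coefficient curve
#'
#' The default ground truth for the FLM coefficient function over 42
#' fortnightly lag windows: a positive lobe in late winter/spring of year
#' t-1 (centred on window 6) and a stronger negative lobe over
#' autumn-winter of year t (centred on window 27, i.e. roughly December
#' t-1 to March t for windows counted from January of t-1). Evaluating
#' this curve at the spline knots and interpolating makes the truth
#' exactly representable by the fitted basis.
#'
#' @param w Window positions at which to evaluate the curve.
#' @return Numeric vector of coefficient values.
#' @export
default_lag_effect <- function(w) {
  0.035 * exp(-((w - 6) / 4)^2) - 0.05 * exp(-((w - 27) / 5)^2)
}

#' Winter-concentrated lag-coefficient curve
#'
#' A single strong negative lobe over the winter windows of year t
#' (centred on fortnight 27, roughly December t-1 to March t), emulating
#' a harsh-winter precipitation effect: wet winters depress survival and
#' fecundity. Used as the ground truth in model-ranking experiments where
#' a concentrated, strong climate signal is required.
#'
#' @param w Window positions at which to evaluate the curve.
#' @param amplitude Depth of the lobe (negative for a harmful effect).
#' @return Numeric vector of coefficient values.
#' @export
winter_lag_effect <- function(w, amplitude = -0.12) {
  amplitude * exp(-((w - 27) / 5)^2)
}
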