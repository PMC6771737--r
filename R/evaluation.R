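log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Restrict a spec's climate data to a subset of years.
spec_for_years <- function(spec, keep) {
  out <- spec
  if (!is.null(spec$Mcov)) out$Mcov <- spec$Mcov[keep]
  if (!is.null(spec$Cmat)) out$Cmat <- spec$Cmat[keep, , drop = FALSE]
  out
}

#' Leave-one-year-out marginal expected log predictive density
#'
#' Cluster cross-validation over whole years: the model is refitted once
#' per study year with that year's demographic outcomes withheld (its
#' density and climate covariates remain available as known covariates).
#' For each retained posterior draw, `M` fresh year-effect pairs are drawn
#' from their fitted bivariate normal law and the held-out year's joint
#' likelihood (product over submodels, binomial coefficient included) is
#' averaged over them; the per-year log predictive density is the log of
#' the average over all (draw, sample) pairs, computed by log-sum-exp.
#' Marginalizing the year effects this way avoids the optimism of
#' conditioning on fitted random effects.
#'
#' @param panel A `"demographic_panel"`.
#' @param spec A `"semflm_spec"`.
#' @param config An `"mcmc_config"` used for every refit (fold seeds
#'   derive from it).
#' @param M Random-effect draws per posterior draw.
#' @param S Posterior draws used per fold (`NULL` = all retained draws).
#' @param folds Indices of the years to hold out (default: every year in
#'   turn). A subset gives a reduced cross-validation whose comparisons
#'   remain valid between models evaluated on the same folds.
#' @param label Model label carried into comparison tables.
#' @return An `"elpd_result"`: list with `per_year_lpd`, `elpd_hat`
#'   (their sum), `per_year_se`, `mc_se`, `S`, `M`, `years`, and
#'   `flagged_years` (years whose refit failed its convergence
#'   diagnostics; never silently included).
#' @export
loyo_elpd <- function(panel, spec, config = mcmc_config(), M = 1000,
                      S = NULL, folds = NULL, label = spec$variant) {
  T_ <- length(panel$years)
  if (T_ < 3) stop("leave-one-year-out needs at least 3 years")
  if (is.null(folds)) folds <- seq_len(T_)
  per_lpd <- per_se <- numeric(length(folds))
  flagged <- logical(length(folds))
  for (f in seq_along(folds)) {
    i <- folds[f]
    train <- setdiff(seq_len(T_), i)
    spec_i <- spec_for_years(spec, train)
    cfg <- config
    cfg$seed <- config$seed + i
    fit <- run_mcmc(subset_years(panel, train), spec_i, cfg)
    di <- try(mcmc_diagnostics(fit), silent = TRUE)
    if (inherits(di, "try-error")) {
      flagged[f] <- TRUE
    } else {
      rh <- di$rhat[is.finite(di$rhat)]
      flagged[f] <- length(rh) > 0 && max(rh) > 1.05
    }
    draws <- fit$draws
    if (!is.null(S) && S < nrow(draws))
      draws <- draws[round(seq(1, nrow(draws), length.out = S)), ,
                     drop = FALSE]
    lay_fold <- param_layout(spec_i, panel$years[train])
    model_i <- build_model_list(subset_years(panel, i),
                                spec_for_years(spec, i), lay_fold)
    draws <- draws_to_internal(draws, spec, lay_fold)
    lme <- with_seed(config$seed + 100000L + i,
                     cpp_marginal_lpd(draws, model_i, as.integer(M)))
    n_s <- length(lme)
    per_lpd[f] <- log_sum_exp(lme) - log(n_s)
    ratio <- exp(lme - per_lpd[f])   # normalized per-draw means, mean 1
    per_se[f] <- sd(ratio) / sqrt(n_s)
  }
  structure(list(per_year_lpd = per_lpd, elpd_hat = sum(per_lpd),
                 per_year_se = per_se, mc_se = sqrt(sum(per_se^2)),
                 S = if (is.null(S))
                   config$n_chains * config$n_iter %/% config$thin else S,
                 M = M, years = panel$years[folds], flagged_years = flagged,
                 label = label),
            class = "elpd_result")
}

#' Compare two models on the deviance scale
#'
#' Returns `-2 (elpd_A - elpd_B)`: negative values favour model A (the
#' candidate) over model B (the baseline). Results computed on different
#' year sets are incomparable and raise an error.
#'
#' @param a,b `"elpd_result"` objects for the two models.
#' @return Scalar deviance-scale difference.
#' @export
compare_models <- function(a, b) {
  if (!identical(a$years, b$years))
    stop("incomparable elpd results: different year sets")
  -2 * (a$elpd_hat - b$elpd_hat)
}

#' Bayesian R-squared of the first environmental axis
#'
#' Per retained draw, the proportion of variance in the first axis
#' explained by its fixed effects (density, temporal trend and any
#' climate terms): `R2 = Var_years(fixed) / (Var_years(fixed) +
#' sigma_e^2)`, where the residual term is the year-effect variance.
#' Reports the posterior median and 95% quantiles.
#'
#' @param post A `"semflm_posterior"`.
#' @param panel The fitted panel.
#' @param spec The fitted spec.
#' @return List with `median`, `lower`, `upper` (2.5/97.5% quantiles) and
#'   the per-draw values in `draws`.
#' @export
bayes_r2 <- function(post, panel, spec) {
  dr <- post$draws
  T_ <- length(panel$years)
  n <- nrow(dr)
  cc <- matrix(0, n, T_)
  if (spec$climate_type == 1L)
    cc <- dr[, "beta_m"] %o% spec$Mcov
  if (spec$climate_type == 2L) {
    X <- spec$Cmat %*% spec$term$basis
    cc <- dr[, grep("^gamma", colnames(dr)), drop = FALSE] %*% t(X)
  }
  fixed <- matrix(panel$density, n, T_, byrow = TRUE) - cc -
    dr[, "alpha_t"] %o% panel$t
  v <- apply(fixed, 1, var)
  if (max(v) < 1e-12)
    stop("undefined R2: the fixed part of the axis has zero variance across years")
  r2 <- v / (v + dr[, "sigma_e"]^2)
  qs <- quantile(r2, c(0.5, 0.025, 0.975), names = FALSE)
  list(median = qs[1], lower = qs[2], upper = qs[3], draws = r2)
}

#' Simulate one replicate panel from a posterior draw
#'
#' Draws replicate successes for every cell (same trial counts) from the
#' binomial model implied by a single posterior draw, including its
#' fitted year effects.
#'
#' @param post A `"semflm_posterior"`.
#' @param panel The fitted panel.
#' @param spec The fitted spec.
#' @param draw Row index of the draw to use.
#' @param seed Integer seed.
#' @return A `"demographic_panel"` with replicate successes.
#' @export
simulate_replicate <- function(post, panel, spec, draw, seed = 1) {
  params <- unflatten_params(post$draws[draw, ], spec, post$years)
  p <- plogis(eta_matrix(panel, params, spec))
  with_seed(seed, {
    k <- matrix(0L, nrow(panel$trials), ncol(panel$trials),
                dimnames = dimnames(panel$trials))
    pos <- panel$trials > 0
    k[pos] <- rbinom(sum(pos), panel$trials[pos], p[pos])
    demographic_panel(panel$years, panel$density, panel$trials, k,
                      panel$submodels)
  })
}

#' Posterior predictive check
#'
#' For a subsample of retained draws, replicate successes are simulated
#' for every cell and compared with the observations through the mid-p
#' tail probability `Pr(rep > obs) + 0.5 Pr(rep = obs)` (the mid-p
#' convention keeps the 5% flag rule approximately calibrated for
#' discrete counts). Cells with tail probability outside [0.025, 0.975]
#' are flagged; zero-trial cells are reported as not applicable.
#'
#' @param post A `"semflm_posterior"`.
#' @param panel The panel to check (observed or replicate data).
#' @param spec The fitted spec.
#' @param n_rep Number of posterior draws used for replication.
#' @param seed Integer seed.
#' @return List with `cells` (per-cell data frame: `submodel`, `year`,
#'   `trials`, `observed`, `tail_prob`, `flagged`) and `summary`
#'   (per-submodel share of usable years flagged).
#' @export
posterior_predictive_check <- function(post, panel, spec, n_rep = 500,
                                       seed = 1) {
  n <- nrow(post$draws)
  use <- if (n_rep >= n) seq_len(n) else
    round(seq(1, n, length.out = n_rep))
  S_ <- nrow(panel$trials); T_ <- ncol(panel$trials)
  greater <- equal <- matrix(0, S_, T_)
  pos <- panel$trials > 0
  with_seed(seed, {
    for (s in use) {
      params <- unflatten_params(post$draws[s, ], spec, post$years)
      p <- plogis(eta_matrix(panel, params, spec))
      rep_k <- matrix(0L, S_, T_)
      rep_k[pos] <- rbinom(sum(pos), panel$trials[pos], p[pos])
      greater <- greater + (rep_k > panel$successes)
      equal <- equal + (rep_k == panel$successes)
    }
  })
  tail_prob <- (greater + 0.5 * equal) / length(use)
  tail_prob[!pos] <- NA_real_
  flagged <- tail_prob < 0.025 | tail_prob > 0.975
  cells <- data.frame(
    submodel = rep(rownames(panel$trials), T_),
    year = rep(panel$years, each = S_),
    trials = as.integer(panel$trials),
    observed = as.integer(panel$successes),
    tail_prob = as.numeric(tail_prob),
    flagged = as.logical(flagged)
  )
  summary <- do.call(rbind, lapply(rownames(panel$trials), function(nm) {
    r <- cells[cells$submodel == nm & !is.na(cells$tail_prob), ]
    data.frame(submodel = nm, n_years_used = nrow(r),
               share_flagged = if (nrow(r)) mean(r$flagged) else NA_real_)
  }))
  list(cells = cells, summary = summary)
}

#' Observed versus predicted yearly proportions
#'
#' Predictions use the posterior-median parameters and the per-year
#' posterior-median random effects; the Pearson correlation between
#' observed and predicted yearly success proportions is reported per
#' submodel over the years with at least one trial. Correlations are
#' reported as `NA` when fewer than 3 usable years exist or either series
#' is constant.
#'
#' @param post A `"semflm_posterior"`.
#' @param panel The fitted panel.
#' @param spec The fitted spec.
#' @return Data frame with columns `submodel`, `correlation`, `n_years`.
#' @export
obs_vs_pred <- function(post, panel, spec) {
  params <- posterior_median_params(post)
  p <- plogis(eta_matrix(panel, params, spec))
  out <- lapply(seq_len(nrow(panel$trials)), function(i) {
    use <- panel$trials[i, ] > 0
    r <- NA_real_
    if (sum(use) >= 3) {
      obs <- panel$successes[i, use] / panel$trials[i, use]
      pred <- p[i, use]
      if (sd(obs) > 0 && sd(pred) > 0) r <- cor(obs, pred)
    }
    data.frame(submodel = rownames(panel$trials)[i], correlation = r,
               n_years = sum(use))
  })
  do.call(rbind, out)
}

#' Screen covariates against the second environmental axis
#'
#' Per retained draw, the Pearson correlation between the second-axis
#' year effects and each supplied per-year covariate (density, year
#' index, sex ratio, ...); reports the posterior median and 95% interval.
#' Constant covariates give an undefined correlation, reported as `NA`.
#'
#' @param post A `"semflm_posterior"` from a two-axis fit.
#' @param covariates Named list (or data frame) of per-year numeric
#'   covariates.
#' @return Data frame with columns `covariate`, `median`, `lower`,
#'   `upper`.
#' @export
axis_covariate_screen <- function(post, covariates) {
  ef_cols <- grep("^eps_f\\.", colnames(post$draws))
  if (!length(ef_cols))
    stop("posterior has no second-axis year effects")
  ef <- post$draws[, ef_cols, drop = FALSE]
  covariates <- as.list(covariates)
  out <- lapply(names(covariates), function(nm) {
    x <- as.numeric(covariates[[nm]])
    if (length(x) != ncol(ef))
      stop("covariate '", nm, "' length does not match the number of years")
    if (sd(x) == 0)
      return(data.frame(covariate = nm, median = NA_real_, lower = NA_real_,
                        upper = NA_real_))
    r <- apply(ef, 1, cor, y = x)
    qs <- quantile(r, c(0.5, 0.025, 0.975), names = FALSE)
    data.frame(covariate = nm, median = qs[1], lower = qs[2], upper = qs[3])
  })
  do.call(rbind, out)
}
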