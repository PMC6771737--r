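#' MCMC configuration
#'
#' The desk-scale default (3 chains, 10^4 burn-in, 5x10^4 post-burn-in
#' iterations thinned by 25) retains 6000 draws in a few seconds on one
#' CPU. [paper_mcmc_config()] returns the original study protocol (2
#' chains, 10^5 burn-in, 6x10^6 iterations thinned by 2000, also 6000
#' retained draws).
#'
#' @param n_chains Number of chains.
#' @param n_iter Post-burn-in iterations per chain; must be divisible by
#'   `thin`. Retained draws per chain are exactly `n_iter / thin`.
#' @param n_burnin Burn-in iterations (discarded; proposal adaptation
#'   happens only here).
#' @param thin Thinning interval.
#' @param seed Integer seed; all chain seeds derive from it.
#' @param init_jitter SD of the per-chain jitter applied to the
#'   initialization point.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 5e4, n_burnin = 1e4,
                        thin = 25, seed = 1, init_jitter = 0.1) {
  if (n_iter %% thin != 0) stop("n_iter must be divisible by thin")
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin), thin = as.integer(thin),
                 seed = as.integer(seed), init_jitter = init_jitter),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @export
paper_mcmc_config <- function(seed = 1) {
  mcmc_config(n_chains = 2, n_iter = 6e6, n_burnin = 1e5, thin = 2000,
              seed = seed)
}

# Assemble the data/model list consumed by the C++ sampler.
build_model_list <- function(panel, spec, lay) {
  sub <- spec$submodels
  T_ <- length(panel$years)
  theta_pos <- rep(-1L, nrow(sub))
  theta_pos[sub$thresholded] <- seq_len(sum(sub$thresholded)) - 1L
  loaded_pos <- rep(-1L, nrow(sub))
  loaded_pos[sub$second_axis] <- seq_len(sum(sub$second_axis)) - 1L
  off <- function(k) if (is.null(lay$idx[[k]])) -1L else
    as.integer(lay$idx[[k]][1] - 1L)
  bf_names <- sub$name[sub$second_axis]
  pr <- spec$priors
  list(
    trials = matrix(as.integer(panel$trials), nrow(sub), T_),
    succ = matrix(as.integer(panel$successes), nrow(sub), T_),
    lch = lchoose(panel$trials, panel$successes),
    D = panel$density, tc = panel$t,
    thresholded = as.integer(sub$thresholded),
    theta_pos = theta_pos, loaded_pos = loaded_pos,
    two_axis = spec$two_axis, climate_type = spec$climate_type,
    Mcov = if (is.null(spec$Mcov)) numeric(T_) else spec$Mcov,
    X = if (spec$climate_type == 2L) spec$Cmat %*% spec$term$basis
        else matrix(0, T_, 0),
    beta0_flat = identical(pr$beta0, "flat_prob"),
    beta0_sd = pr$beta0_sd, slope_sd = pr$slope_sd,
    beta_e_sd = pr$beta_e_sd, gamma_sd = pr$gamma_sd,
    sigma_scale = pr$sigma_scale,
    theta_lo = if (is.null(spec$theta_range)) 0 else spec$theta_range[1],
    theta_hi = if (is.null(spec$theta_range)) 1 else spec$theta_range[2],
    e_center = if (is.null(spec$axis_center)) mean(panel$density)
               else spec$axis_center,
    bf_con = if (spec$two_axis) as.integer(bf_names == "repro.ad")
             else integer(0),
    offsets = list(beta0 = off("beta0"), beta_t = off("beta_t"),
                   beta_e = off("beta_e"), theta = off("theta"),
                   alpha_t = off("alpha_t"), sigma_e = off("sigma_e"),
                   rho_ef = off("rho_ef"), beta_f = off("beta_f"),
                   beta_m = off("beta_m"), gamma = off("gamma"),
                   eps_e = off("eps_e"), eps_f = off("eps_f")),
    seg = lay$seg, aux = lay$aux
  )
}

# The sampler's internal state stores centered intercepts for
# non-thresholded submodels (rate-logit at mean observed density); the
# user-facing convention everywhere else is the raw intercept
# b0 = b0c + beta_e * mean(e). These helpers convert flat vectors /
# draw matrices between the two.
centered_idx <- function(spec, lay) {
  nt <- which(!spec$submodels$thresholded)
  list(b0 = lay$idx$beta0[nt], be = lay$idx$beta_e[nt],
       ec = if (is.null(spec$axis_center)) 0 else spec$axis_center)
}

draws_to_raw <- function(draws, spec, lay) {
  ci <- centered_idx(spec, lay)
  for (q in seq_along(ci$b0))
    draws[, ci$b0[q]] <- draws[, ci$b0[q]] + draws[, ci$be[q]] * ci$ec
  draws
}

draws_to_internal <- function(draws, spec, lay) {
  ci <- centered_idx(spec, lay)
  for (q in seq_along(ci$b0))
    draws[, ci$b0[q]] <- draws[, ci$b0[q]] - draws[, ci$be[q]] * ci$ec
  draws
}

vec_to_internal <- function(v, spec, lay) {
  ci <- centered_idx(spec, lay)
  v[ci$b0] <- v[ci$b0] - v[ci$be] * ci$ec
  v
}

# Deterministic base initialization point (before per-chain jitter).
# Intercepts start at the empirical pooled logit of each submodel.
# Loadings start at +3: the axis carries density with unit coefficient,
# so positive loadings (vital rates declining as the axis rises) are the
# model's sign convention, and starting in that basin keeps chains away
# from the inferior mirror-image mode (all loadings negative, year
# effects reconstructing a reflected axis).
base_init <- function(spec, lay, panel) {
  v <- numeric(lay$P)
  names(v) <- lay$names
  k <- rowSums(panel$successes)
  n <- rowSums(panel$trials)
  v[lay$idx$beta0] <- pmin(pmax(qlogis((k + 0.5) / (n + 1)), -4), 4)
  v[lay$idx$beta_e] <- 3
  if (!is.null(lay$idx$theta))
    v[lay$idx$theta] <- mean(spec$theta_range)
  # start with a small year-effect SD so the likelihood anchors the axis
  # (and its sign) through density before the variance opens up; a large
  # initial sigma_e lets early year effects absorb a mirror-image axis
  v[lay$idx$sigma_e] <- 0.1
  if (spec$two_axis) {
    bf_names <- spec$submodels$name[spec$submodels$second_axis]
    v[lay$idx$beta_f] <- ifelse(bf_names == "repro.ad", 0.5, 0)
  }
  if (!is.null(spec$fixed)) {
    bad <- setdiff(names(spec$fixed), lay$names)
    # fixed year effects of years outside this panel (e.g. the held-out
    # year during cross-validation) are simply not parameters here
    bad <- bad[!grepl("^eps_[ef]\\.", bad)]
    if (length(bad)) stop("unknown fixed parameter(s): ",
                          paste(bad, collapse = ", "))
    fx <- spec$fixed[names(spec$fixed) %in% lay$names]
    v[names(fx)] <- fx
    # fixed values are given in the raw convention; translate the
    # intercepts of non-thresholded submodels to the internal centered one
    nt_names <- spec$submodels$name[!spec$submodels$thresholded]
    for (nm in nt_names) {
      b0n <- paste0("beta0.", nm)
      ben <- paste0("beta_e.", nm)
      if (b0n %in% names(spec$fixed)) {
        if (!ben %in% names(spec$fixed))
          stop("fixing ", b0n, " requires also fixing ", ben)
        ec <- if (is.null(spec$axis_center)) 0 else spec$axis_center
        v[b0n] <- spec$fixed[[b0n]] - spec$fixed[[ben]] * ec
      }
    }
  }
  v
}

jitter_init <- function(v, spec, lay, free, sd) {
  seg <- lay$seg
  unb <- seg %in% c(1L, 2L, 3L, 5L, 9L, 10L, 11L, 12L)
  v[free & unb] <- v[free & unb] + rnorm(sum(free & unb), 0, sd)
  js <- free & seg == 6L
  v[js] <- v[js] * exp(rnorm(sum(js), 0, sd))
  jt <- free & seg == 4L
  if (any(jt)) {
    rng <- spec$theta_range
    v[jt] <- pmin(pmax(v[jt] + rnorm(sum(jt), 0, sd * 0.1), rng[1] + 1e-6),
                  rng[2] - 1e-6)
  }
  jf <- free & seg == 8L
  if (any(jf)) v[jf] <- abs(v[jf] + rnorm(sum(jf), 0, sd))
  v
}

# Per-segment initial proposal scales (refined during burn-in adaptation).
default_steps <- function(lay) {
  c(`1` = 0.2, `2` = 0.02, `3` = 0.15, `4` = 0.02, `5` = 0.01, `6` = 0.05,
    `7` = 0.1, `8` = 0.2, `9` = 0.05, `10` = 0.05, `11` = 0.1,
    `12` = 0.2)[as.character(lay$seg)]
}

#' Sample the joint posterior by adaptive Metropolis-within-Gibbs
#'
#' Runs the block random-walk Metropolis sampler: during the first half of
#' burn-in every free parameter is updated singly with its own adapted
#' step (target acceptance 0.44); afterwards the parameters are updated in
#' blocks (per-submodel fixed effects; axis trend plus climate
#' coefficients; variance/correlation; second-axis loadings; each year's
#' effect pair jointly) with a block step multiplier adapted toward 0.234.
#' Adaptation stops at the end of burn-in. Chains are run sequentially
#' with seeds derived from `config$seed` and are reproducible bit-for-bit.
#'
#' @param panel A `"demographic_panel"`.
#' @param spec A `"semflm_spec"`.
#' @param config An `"mcmc_config"`.
#' @return An object of class `"semflm_posterior"`: list with `draws`
#'   (retained-draw x parameter matrix, named columns), `chain` (integer
#'   chain label per draw), `accept` (per-chain post-burn-in block
#'   acceptance rates), `config`, `spec`, `n_years`, and `flags`
#'   (character vector; contains `"acceptance-collapse"` if post-burn-in
#'   acceptance fell below 1%).
#' @export
run_mcmc <- function(panel, spec, config = mcmc_config()) {
  lay <- param_layout(spec, panel$years)
  free <- !(lay$names %in% names(spec$fixed))
  if (!any(free)) stop("no free parameters to sample")
  model <- build_model_list(panel, spec, lay)
  blocksB <- c(build_blocks(spec, lay, free),
               ridge_blocks(spec, lay, free, panel$t, model$Mcov, model$X))
  blocksA <- split_blocks(blocksB)
  steps <- default_steps(lay)
  v0 <- base_init(spec, lay, panel)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  chain_seeds <- sample.int(.Machine$integer.max - 1L, config$n_chains)

  draws <- vector("list", config$n_chains)
  accept <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(chain_seeds[ch])
    init <- NULL
    for (try in 1:20) {
      cand <- jitter_init(v0, spec, lay, free, config$init_jitter)
      if (is.finite(cpp_log_posterior(cand, model))) { init <- cand; break }
    }
    if (is.null(init))
      stop("initialization failed: no finite log posterior after 20 tries")
    res <- cpp_run_chain(init, model, blocksA, blocksB,
                         config$n_iter, config$n_burnin,
                         as.integer(floor(config$n_burnin / 2)),
                         config$thin, steps)
    d <- res$draws
    colnames(d) <- lay$names
    draws[[ch]] <- d
    accept[[ch]] <- res$accept
  }
  all_draws <- draws_to_raw(do.call(rbind, draws), spec, lay)
  if (any(!is.finite(all_draws))) stop("sampler produced non-finite draws")
  flags <- character(0)
  mean_acc <- mean(unlist(accept), na.rm = TRUE)
  if (is.finite(mean_acc) && mean_acc < 0.01) {
    flags <- "acceptance-collapse"
    warning("post-burn-in acceptance rate below 1%; chains may not be mixing")
  }
  structure(list(
    draws = all_draws,
    chain = rep(seq_len(config$n_chains), each = nrow(draws[[1]])),
    accept = accept, config = config, spec = spec,
    n_years = length(panel$years), years = panel$years,
    flags = flags
  ), class = "semflm_posterior")
}

#' @export
print.semflm_posterior <- function(x, ...) {
  cat("semflm posterior:", nrow(x$draws), "retained draws x",
      ncol(x$draws), "parameters,", length(unique(x$chain)), "chains\n")
  invisible(x)
}

split_rhat_one <- function(x, chain) {
  halves <- unlist(lapply(split(x, chain), function(v) {
    n2 <- floor(length(v) / 2)
    list(v[seq_len(n2)], v[n2 + seq_len(n2)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- length(halves[[1]])
  if (n < 2) return(NA_real_)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_one <- function(x, chain) {
  per_chain <- split(x, chain)
  total <- 0
  for (v in per_chain) {
    n <- length(v)
    if (sd(v) == 0) return(NA_real_)
    rho <- as.numeric(acf(v, lag.max = min(n - 1, 250),
                          plot = FALSE)$acf)[-1]
    # Geyer initial positive sequence truncation on lag pairs
    tau <- 1
    k <- 1
    while (k + 1 <= length(rho)) {
      pair <- rho[k] + rho[k + 1]
      if (pair <= 0) break
      tau <- tau + 2 * pair
      k <- k + 2
    }
    total <- total + n / tau
  }
  total
}

#' Convergence diagnostics
#'
#' Per-parameter split-Rhat and effective sample size. Parameters with
#' zero sampling variance (e.g. a degenerate chain) are reported with `NA`
#' diagnostics and flagged rather than raising an error; parameters with
#' split-Rhat above 1.05 are flagged.
#'
#' @param post A `"semflm_posterior"`.
#' @return Data frame with columns `param`, `rhat`, `ess`, `flag`.
#' @export
mcmc_diagnostics <- function(post) {
  if (length(unique(post$chain)) < 2)
    stop("diagnostics unavailable: at least 2 chains required")
  if (nrow(post$draws) < 100)
    stop("diagnostics unavailable: fewer than 100 retained draws")
  rhat <- apply(post$draws, 2, split_rhat_one, chain = post$chain)
  ess <- apply(post$draws, 2, ess_one, chain = post$chain)
  data.frame(param = colnames(post$draws), rhat = rhat, ess = ess,
             flag = is.na(rhat) | rhat > 1.05, row.names = NULL)
}

#' Posterior medians as a parameter object
#'
#' Convenience accessor: column-wise posterior medians arranged as a
#' `"semflm_params"` object (year effects included).
#'
#' @param post A `"semflm_posterior"`.
#' @return A `"semflm_params"` object.
#' @export
posterior_median_params <- function(post) {
  med <- apply(post$draws, 2, median)
  unflatten_params(med, post$spec, post$years)
}
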