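# Flat parameter-vector layout shared by the R model functions, the C++
# sampler and the posterior draw matrices. Segment codes (used by the C++
# prior evaluation): 1 beta0, 2 beta_t, 3 beta_e, 4 theta, 5 alpha_t,
# 6 sigma_e, 7 rho_ef, 8 beta_f, 9 beta_m, 10 gamma, 11 eps_e, 12 eps_f.

param_layout <- function(spec, years) {
  n_years <- length(years)
  sub <- spec$submodels
  S <- nrow(sub)
  nm <- sub$name
  names_ <- character(0); seg <- integer(0); aux <- integer(0)
  add <- function(n, s, a) {
    names_ <<- c(names_, n); seg <<- c(seg, rep(s, length(n)))
    aux <<- c(aux, a)
  }
  add(paste0("beta0.", nm), 1L, seq_len(S) - 1L)
  add(paste0("beta_t.", nm), 2L, seq_len(S) - 1L)
  add(paste0("beta_e.", nm), 3L, seq_len(S) - 1L)
  if (any(sub$thresholded))
    add(paste0("theta.", nm[sub$thresholded]), 4L, which(sub$thresholded) - 1L)
  add("alpha_t", 5L, 0L)
  add("sigma_e", 6L, 0L)
  if (spec$two_axis) {
    add("rho_ef", 7L, 0L)
    add(paste0("beta_f.", nm[sub$second_axis]), 8L,
        seq_len(sum(sub$second_axis)) - 1L)
  }
  if (spec$climate_type == 1L) add("beta_m", 9L, 0L)
  if (spec$climate_type == 2L)
    add(paste0("gamma", seq_len(ncol(spec$term$basis))), 10L,
        seq_len(ncol(spec$term$basis)) - 1L)
  add(paste0("eps_e.", years), 11L, seq_len(n_years) - 1L)
  if (spec$two_axis)
    add(paste0("eps_f.", years), 12L, seq_len(n_years) - 1L)
  idx <- split(seq_along(seg), seg)
  names(idx) <- c("beta0", "beta_t", "beta_e", "theta", "alpha_t", "sigma_e",
                  "rho_ef", "beta_f", "beta_m", "gamma", "eps_e",
                  "eps_f")[as.integer(names(idx))]
  list(names = names_, seg = seg, aux = aux, idx = idx, P = length(seg),
       n_years = n_years, S = S)
}

#' Parameter names of a model specification
#'
#' The column names of posterior draw matrices and the names accepted by
#' the `fixed` argument of [model_spec()].
#'
#' Year-effect parameters are named by their year label
#' (e.g. `eps_e.1985`).
#'
#' @param spec A `"semflm_spec"`.
#' @param years Study-year labels.
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec, years) param_layout(spec, years)$names

flatten_params <- function(params, spec, years) {
  lay <- param_layout(spec, years)
  v <- numeric(lay$P)
  names(v) <- lay$names
  v[lay$idx$beta0] <- params$beta0
  v[lay$idx$beta_t] <- params$beta_t
  v[lay$idx$beta_e] <- params$beta_e
  if (!is.null(lay$idx$theta)) v[lay$idx$theta] <- params$theta
  v[lay$idx$alpha_t] <- params$alpha_t
  v[lay$idx$sigma_e] <- params$sigma_e
  if (spec$two_axis) {
    v[lay$idx$rho_ef] <- params$rho_ef
    v[lay$idx$beta_f] <- params$beta_f
  }
  if (spec$climate_type == 1L) v[lay$idx$beta_m] <- params$beta_m
  if (spec$climate_type == 2L) v[lay$idx$gamma] <- params$gamma
  v[lay$idx$eps_e] <- params$eps_e
  if (spec$two_axis) v[lay$idx$eps_f] <- params$eps_f
  v
}

unflatten_params <- function(v, spec, years) {
  lay <- param_layout(spec, years)
  sub <- spec$submodels
  grab <- function(k) if (is.null(lay$idx[[k]])) NULL else unname(v[lay$idx[[k]]])
  structure(list(
    beta0 = setNames(grab("beta0"), sub$name),
    beta_t = setNames(grab("beta_t"), sub$name),
    beta_e = setNames(grab("beta_e"), sub$name),
    theta = if (any(sub$thresholded))
      setNames(grab("theta"), sub$name[sub$thresholded]) else NULL,
    beta_f = if (spec$two_axis)
      setNames(grab("beta_f"), sub$name[sub$second_axis]) else NULL,
    alpha_t = grab("alpha_t"),
    sigma_e = grab("sigma_e"),
    rho_ef = if (spec$two_axis) grab("rho_ef") else 0,
    beta_m = grab("beta_m"),
    gamma = grab("gamma"),
    eps_e = grab("eps_e"),
    eps_f = grab("eps_f")
  ), class = "semflm_params")
}

# Sampler blocks. Each block is a list(idx = 0-based free parameter
# indices, type, aux): type 1 = submodel fixed effects (aux = submodel,
# 0-based), 2 = axis/climate coefficients, 3 = variance/correlation,
# 4 = second-axis loadings, 5 = one year's effect pair (aux = year,
# 0-based). Fixed parameters are removed; empty blocks dropped.
build_blocks <- function(spec, lay, free) {
  sub <- spec$submodels
  blocks <- list()
  push <- function(ii, type, aux) {
    ii <- ii[free[ii]]
    if (length(ii))
      blocks[[length(blocks) + 1L]] <<- list(idx = as.integer(ii - 1L),
                                             type = as.integer(type),
                                             aux = as.integer(aux))
  }
  for (i in seq_len(lay$S)) {
    ii <- c(lay$idx$beta0[i], lay$idx$beta_t[i], lay$idx$beta_e[i])
    if (sub$thresholded[i])
      ii <- c(ii, lay$idx$theta[match(i, which(sub$thresholded))])
    push(ii, 1L, i - 1L)
  }
  push(c(lay$idx$alpha_t, lay$idx$beta_m, lay$idx$gamma), 2L, 0L)
  push(c(lay$idx$sigma_e, lay$idx$rho_ef), 3L, 0L)
  if (spec$two_axis) push(lay$idx$beta_f, 4L, 0L)
  for (t in seq_len(lay$n_years)) {
    ii <- lay$idx$eps_e[t]
    if (spec$two_axis) ii <- c(ii, lay$idx$eps_f[t])
    push(ii, 5L, t - 1L)
  }
  blocks
}

# Ridge blocks (type 6): joint moves of one axis coefficient (alpha_t,
# beta_m or a gamma component) and all first-axis year effects that leave
# the axis values e(t) — and hence the likelihood — invariant. A shift
# delta of the coefficient changes e(t) by -v_t * delta (v_t = centered
# year index, scalar covariate, or FLM design column), which is undone by
# shifting eps_e_t by -v_t * delta. These prior-only moves decorrelate
# the axis coefficients from the year effects.
ridge_blocks <- function(spec, lay, free, tc, Mcov, X) {
  if (!all(free[lay$idx$eps_e])) return(list())
  out <- list()
  push <- function(j, v) {
    if (free[j])
      out[[length(out) + 1L]] <<- list(
        idx = as.integer(c(j, lay$idx$eps_e) - 1L), type = 6L, aux = 0L,
        vr = as.numeric(v))
  }
  push(lay$idx$alpha_t, tc)
  if (!is.null(lay$idx$beta_m)) push(lay$idx$beta_m, Mcov)
  if (!is.null(lay$idx$gamma))
    for (k in seq_along(lay$idx$gamma)) push(lay$idx$gamma[k], X[, k])
  # type 7: the soft ridge between the first-axis loadings of the
  # second-axis submodels and the second-axis year effects. A shift
  # eps_f_t += delta * (e_t - center), beta_e_i += beta_f_i * delta leaves
  # every linear predictor invariant; only the year-effect prior resists
  # it. The proposal coefficients involve only unmoved coordinates
  # (beta_f, e), so the move is symmetric.
  if (spec$two_axis && !is.null(lay$idx$eps_f)) {
    loaded <- which(spec$submodels$second_axis)
    ii <- c(lay$idx$beta_e[loaded], lay$idx$eps_f)
    if (all(free[ii]))
      out[[length(out) + 1L]] <- list(idx = as.integer(ii - 1L), type = 7L,
                                      aux = 0L)
    # type 8: second-axis sign-flip involution. Negating the unconstrained
    # loadings, the correlation and every eps_f is a deterministic
    # symmetric proposal (its own inverse) under which the priors are
    # exactly invariant; only the rows of the positivity-constrained
    # submodel change likelihood. It lets chains escape the reflected
    # pseudo-mode that the sign constraint alone leaves reachable.
    bf_names <- spec$submodels$name[spec$submodels$second_axis]
    jj <- c(lay$idx$beta_f[bf_names != "repro.ad"], lay$idx$rho_ef,
            lay$idx$eps_f)
    if (all(free[jj]))
      out[[length(out) + 1L]] <- list(idx = as.integer(jj - 1L), type = 8L,
                                      aux = 0L)
  }
  out
}

# Phase-A singleton blocks: one coordinate each, inheriting the cache
# type/aux of the containing block. Ridge blocks are phase-B only.
split_blocks <- function(blocks) {
  out <- list()
  for (b in blocks) {
    if (b$type >= 6L) next
    for (j in b$idx)
      out[[length(out) + 1L]] <- list(idx = j, type = b$type, aux = b$aux)
  }
  out
}
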