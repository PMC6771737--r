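// Adaptive random-walk Metropolis-within-Gibbs sampler for the latent-axis
// demographic SEM, plus the Monte-Carlo marginal predictive density kernel
// used by leave-one-year-out cross-validation. Likelihood updates are
// incremental: each proposal block only recomputes the panel cells it can
// affect. Two devices keep mixing healthy despite the strong posterior
// correlations induced by an un-standardized density covariate: (i) the
// sampler state stores *centered* intercepts for non-thresholded submodels
// (eta = b0c + bt*t - be*(e - e_center), so b0c is the rate-logit at
// average density and is nearly orthogonal to the loading; the R wrapper
// converts to/from the raw intercept b0 = b0c + be*e_center), and (ii)
// dedicated prior-only blocks move an axis coefficient together with all
// first-axis year effects so that e(t) is left invariant (symmetric linear
// proposals; Metropolis ratios unaffected). All randomness comes from the
// R RNG, so runs are reproducible given set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.9189385332046727;

struct Model {
  IntegerMatrix trials, succ;
  NumericMatrix lch;            // precomputed lchoose(trials, succ)
  NumericVector D, tc;
  IntegerVector thresholded, theta_pos, loaded_pos;
  bool two_axis;
  int climate_type;             // 0 none, 1 scalar, 2 FLM
  NumericVector Mcov;
  NumericMatrix X;              // T x K design (= C %*% B) for FLM
  bool beta0_flat;
  double beta0_sd, slope_sd, beta_e_sd, gamma_sd, sigma_scale;
  double theta_lo, theta_hi, e_center;
  IntegerVector bf_con;         // 1 = positivity-constrained beta_f entry
  int S, T, K;
  int o_beta0, o_beta_t, o_beta_e, o_theta, o_alpha, o_sigma, o_rho,
      o_bf, o_bm, o_gamma, o_epse, o_epsf;
  IntegerVector seg, aux;
};

static Model make_model(const List& m) {
  Model md;
  md.trials = as<IntegerMatrix>(m["trials"]);
  md.succ = as<IntegerMatrix>(m["succ"]);
  md.lch = as<NumericMatrix>(m["lch"]);
  md.D = as<NumericVector>(m["D"]);
  md.tc = as<NumericVector>(m["tc"]);
  md.thresholded = as<IntegerVector>(m["thresholded"]);
  md.theta_pos = as<IntegerVector>(m["theta_pos"]);
  md.loaded_pos = as<IntegerVector>(m["loaded_pos"]);
  md.two_axis = as<bool>(m["two_axis"]);
  md.climate_type = as<int>(m["climate_type"]);
  md.Mcov = as<NumericVector>(m["Mcov"]);
  md.X = as<NumericMatrix>(m["X"]);
  md.beta0_flat = as<bool>(m["beta0_flat"]);
  md.beta0_sd = as<double>(m["beta0_sd"]);
  md.slope_sd = as<double>(m["slope_sd"]);
  md.beta_e_sd = as<double>(m["beta_e_sd"]);
  md.gamma_sd = as<double>(m["gamma_sd"]);
  md.sigma_scale = as<double>(m["sigma_scale"]);
  md.theta_lo = as<double>(m["theta_lo"]);
  md.theta_hi = as<double>(m["theta_hi"]);
  md.e_center = as<double>(m["e_center"]);
  md.bf_con = as<IntegerVector>(m["bf_con"]);
  md.S = md.trials.nrow();
  md.T = md.trials.ncol();
  md.K = md.X.ncol();
  List off = m["offsets"];
  md.o_beta0 = as<int>(off["beta0"]);  md.o_beta_t = as<int>(off["beta_t"]);
  md.o_beta_e = as<int>(off["beta_e"]); md.o_theta = as<int>(off["theta"]);
  md.o_alpha = as<int>(off["alpha_t"]); md.o_sigma = as<int>(off["sigma_e"]);
  md.o_rho = as<int>(off["rho_ef"]);   md.o_bf = as<int>(off["beta_f"]);
  md.o_bm = as<int>(off["beta_m"]);    md.o_gamma = as<int>(off["gamma"]);
  md.o_epse = as<int>(off["eps_e"]);   md.o_epsf = as<int>(off["eps_f"]);
  md.seg = as<IntegerVector>(m["seg"]);
  md.aux = as<IntegerVector>(m["aux"]);
  return md;
}

static inline double softplus(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static inline double dnorm_log(double x, double sd) {
  return -LOG_SQRT_2PI - std::log(sd) - 0.5 * (x / sd) * (x / sd);
}

// binomial log pmf of one cell; zero-trial cells contribute 0.
// log p = -softplus(-eta), log(1-p) = -softplus(-eta) - eta, so
// ll = lchoose - n * softplus(-eta) - (n - k) * eta.
static inline double cell_ll(const Model& md, int i, int t, double eta) {
  double n = md.trials(i, t);
  if (n == 0.0) return 0.0;
  double k = md.succ(i, t);
  return md.lch(i, t) - n * softplus(-eta) - (n - k) * eta;
}

static inline double eta_of(const Model& md, const NumericVector& par,
                            int i, int t, double e_t) {
  double base = par[md.o_beta0 + i] + par[md.o_beta_t + i] * md.tc[t];
  double be = par[md.o_beta_e + i];
  if (md.thresholded[i]) {
    double th = par[md.o_theta + md.theta_pos[i]];
    return (e_t < th) ? base : base - be * (e_t - th);
  }
  double eta = base - be * (e_t - md.e_center);
  if (md.two_axis && md.loaded_pos[i] >= 0)
    eta += par[md.o_bf + md.loaded_pos[i]] * par[md.o_epsf + t];
  return eta;
}

static void climate_vec(const Model& md, const NumericVector& par,
                        std::vector<double>& cc) {
  if (md.climate_type == 1) {
    double bm = par[md.o_bm];
    for (int t = 0; t < md.T; ++t) cc[t] = bm * md.Mcov[t];
  } else if (md.climate_type == 2) {
    for (int t = 0; t < md.T; ++t) {
      double s = 0.0;
      for (int k = 0; k < md.K; ++k) s += md.X(t, k) * par[md.o_gamma + k];
      cc[t] = s;
    }
  } else {
    std::fill(cc.begin(), cc.end(), 0.0);
  }
}

static inline double axis_of(const Model& md, const NumericVector& par,
                             int t, double cc_t) {
  return md.D[t] - cc_t - par[md.o_alpha] * md.tc[t] - par[md.o_epse + t];
}

// log prior density of one scalar parameter (year effects excluded; their
// joint density is handled per-year below)
static double scalar_prior(const Model& md, int j, double x) {
  switch (md.seg[j]) {
  case 1:  // beta0
    if (md.beta0_flat) {
      double a = std::fabs(x);
      return -a - 2.0 * std::log1p(std::exp(-a));
    }
    return dnorm_log(x, md.beta0_sd);
  case 2: return dnorm_log(x, md.slope_sd);      // beta_t
  case 3: return dnorm_log(x, md.beta_e_sd);     // beta_e
  case 4:                                        // theta ~ U(lo, hi)
    if (x < md.theta_lo || x > md.theta_hi) return R_NegInf;
    return -std::log(md.theta_hi - md.theta_lo);
  case 5: return dnorm_log(x, md.slope_sd);      // alpha_t
  case 6:                                        // sigma_e ~ Half-N
    if (x <= 0.0) return R_NegInf;
    return M_LN2 + dnorm_log(x, md.sigma_scale);
  case 7:                                        // rho ~ U(-1, 1)
    if (x <= -1.0 || x >= 1.0) return R_NegInf;
    return -M_LN2;
  case 8:                                        // beta_f
    if (md.bf_con[md.aux[j]]) {
      if (x <= 0.0) return R_NegInf;
      return M_LN2 + dnorm_log(x, md.slope_sd);
    }
    return dnorm_log(x, md.slope_sd);
  case 9: return dnorm_log(x, md.slope_sd);      // beta_m
  case 10: return dnorm_log(x, md.gamma_sd);     // gamma
  default: return 0.0;                           // eps_e / eps_f
  }
}

// joint log density of year t's effects given (sigma_e, rho_ef)
static double year_prior(const Model& md, const NumericVector& par, int t) {
  double s = par[md.o_sigma];
  if (s <= 0.0) return R_NegInf;
  double ee = par[md.o_epse + t];
  if (!md.two_axis) return dnorm_log(ee, s);
  double r = par[md.o_rho];
  if (r <= -1.0 || r >= 1.0) return R_NegInf;
  double ef = par[md.o_epsf + t];
  double om = 1.0 - r * r;
  double q = (ee * ee / (s * s) - 2.0 * r * ee * ef / s + ef * ef) / om;
  return -std::log(2.0 * M_PI) - 0.5 * std::log(s * s * om) - 0.5 * q;
}

static double full_prior(const Model& md, const NumericVector& par) {
  double lp = 0.0;
  for (int j = 0; j < (int)par.size(); ++j) {
    int sg = md.seg[j];
    if (sg == 11 || sg == 12) continue;
    lp += scalar_prior(md, j, par[j]);
    if (!R_finite(lp)) return R_NegInf;
  }
  for (int t = 0; t < md.T; ++t) lp += year_prior(md, par, t);
  return lp;
}

static double full_ll(const Model& md, const NumericVector& par,
                      std::vector<double>& cc, std::vector<double>& e,
                      NumericMatrix& llc) {
  climate_vec(md, par, cc);
  double tot = 0.0;
  for (int t = 0; t < md.T; ++t) {
    e[t] = axis_of(md, par, t, cc[t]);
    for (int i = 0; i < md.S; ++i) {
      double v = cell_ll(md, i, t, eta_of(md, par, i, t, e[t]));
      llc(i, t) = v;
      tot += v;
    }
  }
  return tot;
}

// [[Rcpp::export]]
double cpp_log_posterior(NumericVector par, List model) {
  Model md = make_model(model);
  double lp = full_prior(md, par);
  if (!R_finite(lp)) return R_NegInf;
  std::vector<double> cc(md.T), e(md.T);
  NumericMatrix llc(md.S, md.T);
  return lp + full_ll(md, par, cc, e, llc);
}

// [[Rcpp::export]]
List cpp_run_chain(NumericVector init, List model, List blocksA, List blocksB,
                   int n_iter, int n_burnin, int phaseA_iters, int thin,
                   NumericVector step_init) {
  Model md = make_model(model);
  int P = init.size();
  NumericVector par = clone(init);
  NumericVector stepA = clone(step_init);

  std::vector<double> cc(md.T), e(md.T);
  NumericMatrix llc(md.S, md.T);
  double ll_tot = full_ll(md, par, cc, e, llc);
  double pri = full_prior(md, par);
  if (!R_finite(ll_tot) || !R_finite(pri))
    stop("initialization point has non-finite log posterior");

  int nA = blocksA.size(), nB = blocksB.size();
  std::vector<std::vector<int> > idxA(nA), idxB(nB);
  std::vector<int> typeA(nA), auxA(nA), typeB(nB), auxB(nB);
  std::vector<std::vector<double> > vrB(nB);
  for (int b = 0; b < nA; ++b) {
    List bl = blocksA[b];
    idxA[b] = as<std::vector<int> >(bl["idx"]);
    typeA[b] = as<int>(bl["type"]); auxA[b] = as<int>(bl["aux"]);
  }
  NumericVector multB(nB);
  for (int b = 0; b < nB; ++b) {
    List bl = blocksB[b];
    idxB[b] = as<std::vector<int> >(bl["idx"]);
    typeB[b] = as<int>(bl["type"]); auxB[b] = as<int>(bl["aux"]);
    if (bl.containsElementNamed("vr"))
      vrB[b] = as<std::vector<double> >(bl["vr"]);
    multB[b] = (typeB[b] >= 6) ? 1.0 : 1.0 / std::sqrt((double)idxB[b].size());
  }
  std::vector<long> accB(nB, 0), totB(nB, 0);
  std::vector<long> cntA(nA, 0), cntB(nB, 0);

  int n_keep = n_iter / thin;
  NumericMatrix draws(n_keep, P);
  int kept = 0;

  std::vector<double> new_cc(md.T), new_e(md.T);
  NumericMatrix new_llc(md.S, md.T);
  std::vector<double> old_vals(P);

  RNGScope scope;
  int total_iters = n_burnin + n_iter;
  for (int it = 0; it < total_iters; ++it) {
    bool phA = it < phaseA_iters;
    bool adapting = it < n_burnin;
    int nb = phA ? nA : nB;
    for (int b = 0; b < nb; ++b) {
      const std::vector<int>& ii = phA ? idxA[b] : idxB[b];
      int type = phA ? typeA[b] : typeB[b];
      int aux = phA ? auxA[b] : auxB[b];
      int d = ii.size();
      bool all_years = (type == 3 || type >= 6);

      // old prior contributions (par still at current state)
      double dp = 0.0;
      if (all_years)
        for (int t = 0; t < md.T; ++t) dp -= year_prior(md, par, t);
      if (type == 5) dp -= year_prior(md, par, aux);
      for (int q = 0; q < d; ++q) {
        int j = ii[q];
        int sg = md.seg[j];
        if (sg != 11 && sg != 12) dp -= scalar_prior(md, j, par[j]);
        old_vals[q] = par[j];
      }

      // propose
      if (type == 6) {
        double sc = multB[b] * stepA[ii[0]];
        double delta = sc * norm_rand();
        par[ii[0]] += delta;
        const std::vector<double>& vr = vrB[b];
        for (int q = 1; q < d; ++q) par[ii[q]] -= vr[q - 1] * delta;
      } else if (type == 7) {
        // loading / second-axis ridge: eta-invariant by construction
        double sc = multB[b] * stepA[ii[0]];
        double delta = sc * norm_rand();
        for (int i = 0; i < md.S; ++i)
          if (md.loaded_pos[i] >= 0)
            par[md.o_beta_e + i] += par[md.o_bf + md.loaded_pos[i]] * delta;
        for (int t = 0; t < md.T; ++t)
          par[md.o_epsf + t] += delta * (e[t] - md.e_center);
      } else if (type == 8) {
        // deterministic involution: second-axis sign flip
        for (int q = 0; q < d; ++q) par[ii[q]] = -par[ii[q]];
      } else {
        for (int q = 0; q < d; ++q) {
          int j = ii[q];
          double sc = phA ? stepA[j] : multB[b] * stepA[j];
          par[j] += sc * norm_rand();
        }
      }

      // new prior contributions
      for (int q = 0; q < d; ++q) {
        int j = ii[q];
        int sg = md.seg[j];
        if (sg != 11 && sg != 12) dp += scalar_prior(md, j, par[j]);
      }
      if (R_finite(dp)) {
        if (all_years)
          for (int t = 0; t < md.T; ++t) dp += year_prior(md, par, t);
        if (type == 5) dp += year_prior(md, par, aux);
      }

      bool accept = false;
      if (R_finite(dp)) {
        double dll = 0.0;
        if (type == 1) {                 // one submodel's fixed effects
          int i = aux;
          for (int t = 0; t < md.T; ++t) {
            double v = cell_ll(md, i, t, eta_of(md, par, i, t, e[t]));
            new_llc(i, t) = v;
            dll += v - llc(i, t);
          }
          if (std::log(unif_rand()) < dp + dll) {
            accept = true;
            for (int t = 0; t < md.T; ++t) llc(i, t) = new_llc(i, t);
            ll_tot += dll;
          }
        } else if (type == 2) {          // axis trend + climate coefficients
          climate_vec(md, par, new_cc);
          double tot = 0.0;
          for (int t = 0; t < md.T; ++t) {
            new_e[t] = axis_of(md, par, t, new_cc[t]);
            for (int i = 0; i < md.S; ++i) {
              double v = cell_ll(md, i, t, eta_of(md, par, i, t, new_e[t]));
              new_llc(i, t) = v;
              tot += v;
            }
          }
          dll = tot - ll_tot;
          if (std::log(unif_rand()) < dp + dll) {
            accept = true;
            cc = new_cc; e = new_e;
            std::copy(new_llc.begin(), new_llc.end(), llc.begin());
            ll_tot = tot;
          }
        } else if (type == 3) {          // sigma_e / rho_ef: prior only
          if (std::log(unif_rand()) < dp) accept = true;
        } else if (type == 4) {          // second-axis loadings
          for (int i = 0; i < md.S; ++i) {
            if (md.loaded_pos[i] < 0) continue;
            for (int t = 0; t < md.T; ++t) {
              double v = cell_ll(md, i, t, eta_of(md, par, i, t, e[t]));
              new_llc(i, t) = v;
              dll += v - llc(i, t);
            }
          }
          if (std::log(unif_rand()) < dp + dll) {
            accept = true;
            for (int i = 0; i < md.S; ++i) {
              if (md.loaded_pos[i] < 0) continue;
              for (int t = 0; t < md.T; ++t) llc(i, t) = new_llc(i, t);
            }
            ll_tot += dll;
          }
        } else if (type == 6) {          // e(t)-invariant ridge: prior only
          if (std::log(unif_rand()) < dp) {
            accept = true;
            climate_vec(md, par, cc);    // cc changed if a gamma/beta_m moved
          }
        } else if (type == 7) {          // eta-invariant ridge: prior only
          if (std::log(unif_rand()) < dp) accept = true;
        } else if (type == 8) {          // sign flip: loaded rows only
          for (int i = 0; i < md.S; ++i) {
            if (md.loaded_pos[i] < 0) continue;
            for (int t = 0; t < md.T; ++t) {
              double v = cell_ll(md, i, t, eta_of(md, par, i, t, e[t]));
              new_llc(i, t) = v;
              dll += v - llc(i, t);
            }
          }
          if (std::log(unif_rand()) < dp + dll) {
            accept = true;
            for (int i = 0; i < md.S; ++i) {
              if (md.loaded_pos[i] < 0) continue;
              for (int t = 0; t < md.T; ++t) llc(i, t) = new_llc(i, t);
            }
            ll_tot += dll;
          }
        } else {                         // type 5: one year's effect pair
          int t = aux;
          double et = axis_of(md, par, t, cc[t]);
          for (int i = 0; i < md.S; ++i) {
            double v = cell_ll(md, i, t, eta_of(md, par, i, t, et));
            new_llc(i, t) = v;
            dll += v - llc(i, t);
          }
          if (std::log(unif_rand()) < dp + dll) {
            accept = true;
            e[t] = et;
            for (int i = 0; i < md.S; ++i) llc(i, t) = new_llc(i, t);
            ll_tot += dll;
          }
        }
      }
      if (!accept)
        for (int q = 0; q < d; ++q) par[ii[q]] = old_vals[q];

      if (adapting) {
        if (phA) {
          double g = std::min(0.25, 1.0 / std::sqrt(1.0 + (double)(++cntA[b])));
          stepA[ii[0]] *= std::exp(g * ((accept ? 1.0 : 0.0) - 0.44));
        } else if (type != 8) {
          int dof = (type >= 6) ? 1 : d;
          double target = (dof == 1) ? 0.44 : 0.234;
          double g = std::min(0.25, 1.0 / std::sqrt(1.0 + (double)(++cntB[b])));
          multB[b] *= std::exp(g * ((accept ? 1.0 : 0.0) - target));
        }
      } else if (!phA) {
        totB[b]++;
        if (accept) accB[b]++;
      }
    }
    if (it >= n_burnin && ((it - n_burnin + 1) % thin) == 0) {
      for (int j = 0; j < P; ++j) draws(kept, j) = par[j];
      kept++;
    }
  }

  NumericVector acc_rate(nB);
  for (int b = 0; b < nB; ++b)
    acc_rate[b] = totB[b] > 0 ? (double)accB[b] / (double)totB[b] : NA_REAL;
  return List::create(_["draws"] = draws, _["accept"] = acc_rate,
                      _["steps"] = stepA, _["mult"] = multB,
                      _["final_lp"] = full_prior(md, par) + ll_tot);
}

// Marginal predictive log density of one held-out year: for each posterior
// draw s, average the year's joint likelihood over M fresh draws of the
// year-effect pair; returns log of the per-draw averages (length S), to be
// combined by log-sum-exp in R. The model list describes a single-year
// panel (T = 1) with the full-fit parameter layout.
// [[Rcpp::export]]
NumericVector cpp_marginal_lpd(NumericMatrix draws, List model, int M) {
  Model md = make_model(model);
  if (md.T != 1) stop("cpp_marginal_lpd expects a single-year model");
  int S = draws.nrow();
  NumericVector out(S);
  std::vector<double> lw(M);
  RNGScope scope;
  NumericVector par(draws.ncol());
  for (int s = 0; s < S; ++s) {
    for (int j = 0; j < draws.ncol(); ++j) par[j] = draws(s, j);
    std::vector<double> cc(1);
    climate_vec(md, par, cc);
    double sig = par[md.o_sigma];
    double rho = md.two_axis ? par[md.o_rho] : 0.0;
    double srt = std::sqrt(std::max(0.0, 1.0 - rho * rho));
    double mx = R_NegInf;
    for (int m = 0; m < M; ++m) {
      double z1 = norm_rand();
      if (md.two_axis) {
        double z2 = norm_rand();
        par[md.o_epsf] = rho * z1 + srt * z2;
      }
      par[md.o_epse] = sig * z1;
      double et = axis_of(md, par, 0, cc[0]);
      double ll = 0.0;
      for (int i = 0; i < md.S; ++i)
        ll += cell_ll(md, i, 0, eta_of(md, par, i, 0, et));
      lw[m] = ll;
      if (ll > mx) mx = ll;
    }
    double sum = 0.0;
    for (int m = 0; m < M; ++m) sum += std::exp(lw[m] - mx);
    out[s] = mx + std::log(sum) - std::log((double)M);
  }
  return out;
}
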