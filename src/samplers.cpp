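// MCMC samplers for the over-dispersed Poisson (log link) and Gaussian
// (identity) mixed models.
//
// Poisson: vectorised single-site Metropolis for random-effect levels
// (levels of one term are conditionally independent given all other terms)
// and random-walk Metropolis for fixed effects, with conjugate
// inverse-gamma draws for variance components. Because sums like
// beta0 + mean(u_t) are only weakly identified by the likelihood, each
// iteration also performs likelihood-invariant "sweep" Gibbs moves along
// the confounded directions: intercept vs each term's level mean, each
// treatment-coded fixed effect vs the matching levels of terms containing
// the grouping factor, and each nested term pair (translating mass between
// a term and the finer term it is nested in). These moves leave the
// likelihood untouched, so their conditionals are Gaussian in the priors
// and mix the posterior along directions the single-site updates cannot.
//
// Gaussian: fully conjugate Gibbs with the same sweep moves.
//
// Variance components use the scalar inverse-Wishart convention
// sigma2 ~ IG(nu/2, nu*V/2). All randomness comes from R's RNG, so runs
// are reproducible from set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double ETA_CLAMP = 50.0;

static inline double clamped_exp(double eta) {
  if (eta > ETA_CLAMP) eta = ETA_CLAMP;
  if (eta < -ETA_CLAMP) eta = -ETA_CLAMP;
  return std::exp(eta);
}

static inline double draw_inv_gamma(double shape, double rate) {
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0) g = 1e-300;
  return 1.0 / g;
}

struct SweepPair {
  int a, b;             // term indices: a coarse, b fine (factors(a) subset)
  IntegerVector map;    // level of a for each level of b
};

// Draw s ~ N(mean, 1/prec) for prec = pa + pb, mean = (ma*pa_side...) and
// translate: xa += s, xb[group] -= s. Used for all sweep flavours.

// [[Rcpp::export]]
List mg_sample_poisson(NumericVector y, NumericMatrix X, List term_index,
                       IntegerVector n_levels, NumericVector prior_V,
                       NumericVector prior_nu, double beta_prior_var,
                       List fixed_maps, List sweep_pairs,
                       int nitt, int burnin, int thin,
                       bool use_likelihood) {
  const int n = y.size();
  const int p = X.ncol();
  const int T = term_index.size();
  if (burnin >= nitt) stop("burn_in must be smaller than n_iterations");

  std::vector<IntegerVector> idx(T), fmap(T);
  for (int t = 0; t < T; ++t) {
    idx[t] = as<IntegerVector>(term_index[t]);
    fmap[t] = as<IntegerVector>(fixed_maps[t]);
  }
  std::vector<SweepPair> pairs;
  for (int k = 0; k < sweep_pairs.size(); ++k) {
    List pk = sweep_pairs[k];
    SweepPair sp;
    sp.a = as<int>(pk["a"]);
    sp.b = as<int>(pk["b"]);
    sp.map = as<IntegerVector>(pk["map"]);
    pairs.push_back(sp);
  }

  NumericVector beta(p, 0.0);
  double ybar = 0.0;
  for (int i = 0; i < n; ++i) ybar += y[i];
  ybar = ybar / std::max(n, 1);
  beta[0] = std::log(ybar + 0.5);
  std::vector<NumericVector> u(T);
  NumericVector sigma2(T);
  for (int t = 0; t < T; ++t) {
    u[t] = NumericVector(n_levels[t], 0.0);
    sigma2[t] = prior_V[t];
  }
  NumericVector eta(n), expEta(n);
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    expEta[i] = clamped_exp(e);
  }

  NumericVector step_beta(p, 0.1);
  NumericVector step_u(T, 0.5);
  const double target_acc = 0.44, adapt_rate = 0.05;

  const int ndraws = (nitt - burnin + thin - 1) / thin;
  NumericMatrix beta_draws(ndraws, p);
  NumericMatrix sigma2_draws(ndraws, T);
  List u_draws(T);
  for (int t = 0; t < T; ++t) u_draws[t] = NumericMatrix(ndraws, n_levels[t]);

  std::vector<double> delta, prop, expprop, acc_s, cnt_s;
  std::vector<char> accepted;
  int stored = 0;

  for (int iter = 0; iter < nitt; ++iter) {
    bool adapting = iter < burnin;

    // ---- fixed effects: random-walk Metropolis (0/1 design assumed-free)
    if (use_likelihood) {
      for (int j = 0; j < p; ++j) {
        double eps = R::norm_rand() * step_beta[j];
        double d = 0.0;
        for (int i = 0; i < n; ++i) {
          double x = X(i, j);
          if (x != 0.0) {
            double e1 = eta[i] + x * eps;
            double ex1 = (e1 > -ETA_CLAMP && e1 < ETA_CLAMP && x == 1.0)
                         ? expEta[i] * std::exp(eps) : clamped_exp(e1);
            d += y[i] * x * eps - ex1 + expEta[i];
          }
        }
        double b0 = beta[j], b1 = beta[j] + eps;
        d -= (b1 * b1 - b0 * b0) / (2.0 * beta_prior_var);
        bool acc = std::log(R::unif_rand()) < d;
        if (acc) {
          beta[j] = b1;
          for (int i = 0; i < n; ++i) {
            if (X(i, j) != 0.0) {
              eta[i] += X(i, j) * eps;
              expEta[i] = clamped_exp(eta[i]);
            }
          }
        }
        if (adapting) {
          step_beta[j] *= std::exp(adapt_rate * ((acc ? 1.0 : 0.0) - target_acc));
          if (step_beta[j] < 1e-5) step_beta[j] = 1e-5;
        }
      }
    }

    // ---- random-effect terms: vectorised single-site Metropolis
    for (int t = 0; t < T; ++t) {
      int L = n_levels[t];
      delta.assign(L, 0.0);
      prop.resize(L);
      expprop.resize(L);
      const IntegerVector &ix = idx[t];
      NumericVector &ut = u[t];
      for (int l = 0; l < L; ++l) {
        prop[l] = R::norm_rand() * step_u[t];
        expprop[l] = std::exp(prop[l]);
      }
      if (use_likelihood) {
        for (int i = 0; i < n; ++i) {
          int l = ix[i];
          double e1 = eta[i] + prop[l];
          double ex1 = (e1 > -ETA_CLAMP && e1 < ETA_CLAMP)
                       ? expEta[i] * expprop[l] : clamped_exp(e1);
          delta[l] += y[i] * prop[l] - ex1 + expEta[i];
        }
      }
      int n_acc = 0;
      accepted.assign(L, 0);
      for (int l = 0; l < L; ++l) {
        double u0 = ut[l], u1 = ut[l] + prop[l];
        double d = delta[l] - (u1 * u1 - u0 * u0) / (2.0 * sigma2[t]);
        accepted[l] = std::log(R::unif_rand()) < d;
        if (accepted[l]) { ut[l] = u1; ++n_acc; }
      }
      for (int i = 0; i < n; ++i) {
        int l = ix[i];
        if (accepted[l]) {
          eta[i] += prop[l];
          expEta[i] = clamped_exp(eta[i]);
        }
      }
      if (adapting && L > 0) {
        double acc_rate = (double)n_acc / L;
        step_u[t] *= std::exp(adapt_rate * (acc_rate - target_acc));
        if (step_u[t] < 1e-5) step_u[t] = 1e-5;
      }
    }

    // ---- sweep moves (likelihood-invariant Gibbs along confounded lines)
    for (int t = 0; t < T; ++t) {
      int L = n_levels[t];
      NumericVector &ut = u[t];
      // intercept vs term mean: beta0 += s, u_t -= s
      double sum_u = 0.0;
      for (int l = 0; l < L; ++l) sum_u += ut[l];
      double prec = L / sigma2[t] + 1.0 / beta_prior_var;
      double mean = (sum_u / sigma2[t] - beta[0] / beta_prior_var) / prec;
      double s = mean + R::norm_rand() / std::sqrt(prec);
      beta[0] += s;
      for (int l = 0; l < L; ++l) ut[l] -= s;

      // fixed column j vs the term's levels tied to that column
      const IntegerVector &fm = fmap[t];
      if (fm.size() == L && p > 1) {
        for (int j = 1; j < p; ++j) {
          double su = 0.0;
          int cnt = 0;
          for (int l = 0; l < L; ++l) {
            if (fm[l] == j) { su += ut[l]; ++cnt; }
          }
          if (cnt == 0) continue;
          double pr = cnt / sigma2[t] + 1.0 / beta_prior_var;
          double mn = (su / sigma2[t] - beta[j] / beta_prior_var) / pr;
          double sj = mn + R::norm_rand() / std::sqrt(pr);
          beta[j] += sj;
          for (int l = 0; l < L; ++l) {
            if (fm[l] == j) ut[l] -= sj;
          }
        }
      }
    }
    for (size_t k = 0; k < pairs.size(); ++k) {
      const SweepPair &sp = pairs[k];
      NumericVector &ua = u[sp.a];
      NumericVector &ub = u[sp.b];
      int La = n_levels[sp.a], Lb = n_levels[sp.b];
      acc_s.assign(La, 0.0);
      cnt_s.assign(La, 0.0);
      for (int lb = 0; lb < Lb; ++lb) {
        int la = sp.map[lb];
        acc_s[la] += ub[lb];
        cnt_s[la] += 1.0;
      }
      // per coarse level: ua[la] += s, ub[group la] -= s
      std::vector<double> shift(La);
      for (int la = 0; la < La; ++la) {
        double pr = 1.0 / sigma2[sp.a] + cnt_s[la] / sigma2[sp.b];
        double mn = (acc_s[la] / sigma2[sp.b] - ua[la] / sigma2[sp.a]) / pr;
        shift[la] = mn + R::norm_rand() / std::sqrt(pr);
        ua[la] += shift[la];
      }
      for (int lb = 0; lb < Lb; ++lb) ub[lb] -= shift[sp.map[lb]];
    }

    // ---- conjugate variance updates
    for (int t = 0; t < T; ++t) {
      int L = n_levels[t];
      NumericVector &ut = u[t];
      double ss = 0.0;
      for (int l = 0; l < L; ++l) ss += ut[l] * ut[l];
      sigma2[t] = draw_inv_gamma((prior_nu[t] + L) / 2.0,
                                 (prior_nu[t] * prior_V[t] + ss) / 2.0);
      if (!R_finite(sigma2[t])) stop("degenerate variance update in term %d", t + 1);
    }
    for (int j = 0; j < p; ++j) {
      if (!R_finite(beta[j])) stop("divergent chain: non-finite fixed effect");
    }

    if (iter >= burnin && (iter - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_draws(stored, j) = beta[j];
      for (int t = 0; t < T; ++t) {
        sigma2_draws(stored, t) = sigma2[t];
        NumericMatrix ud = u_draws[t];
        NumericVector &ut = u[t];
        for (int l = 0; l < n_levels[t]; ++l) ud(stored, l) = ut[l];
      }
      ++stored;
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = beta_draws, _["sigma2"] = sigma2_draws,
                      _["u"] = u_draws, _["step_u"] = step_u,
                      _["step_beta"] = step_beta);
}

// [[Rcpp::export]]
List mg_sample_gaussian(NumericVector y, NumericMatrix X, List term_index,
                        IntegerVector n_levels, NumericVector prior_V,
                        NumericVector prior_nu, double resid_V,
                        double resid_nu, double beta_prior_var,
                        List fixed_maps, List sweep_pairs,
                        int nitt, int burnin, int thin,
                        bool use_likelihood) {
  const int n = y.size();
  const int p = X.ncol();
  const int T = term_index.size();
  if (burnin >= nitt) stop("burn_in must be smaller than n_iterations");

  std::vector<IntegerVector> idx(T), fmap(T);
  for (int t = 0; t < T; ++t) {
    idx[t] = as<IntegerVector>(term_index[t]);
    fmap[t] = as<IntegerVector>(fixed_maps[t]);
  }
  std::vector<SweepPair> pairs;
  for (int k = 0; k < sweep_pairs.size(); ++k) {
    List pk = sweep_pairs[k];
    SweepPair sp;
    sp.a = as<int>(pk["a"]);
    sp.b = as<int>(pk["b"]);
    sp.map = as<IntegerVector>(pk["map"]);
    pairs.push_back(sp);
  }

  NumericVector beta(p, 0.0);
  std::vector<NumericVector> u(T);
  NumericVector sigma2(T);
  for (int t = 0; t < T; ++t) {
    u[t] = NumericVector(n_levels[t], 0.0);
    sigma2[t] = prior_V[t];
  }
  double sigma2_e = resid_V;
  NumericVector eta(n, 0.0);

  const int ndraws = (nitt - burnin + thin - 1) / thin;
  NumericMatrix beta_draws(ndraws, p);
  NumericMatrix sigma2_draws(ndraws, T + 1);  // last column: sigma2_e
  List u_draws(T);
  for (int t = 0; t < T; ++t) u_draws[t] = NumericMatrix(ndraws, n_levels[t]);

  std::vector<double> lev_sum, lev_cnt, shift_store, acc_s, cnt_s;
  int stored = 0;

  for (int iter = 0; iter < nitt; ++iter) {
    if (use_likelihood) {
      for (int j = 0; j < p; ++j) {
        double sxx = 0.0, sxr = 0.0;
        for (int i = 0; i < n; ++i) {
          double x = X(i, j);
          if (x != 0.0) {
            double r = y[i] - (eta[i] - x * beta[j]);
            sxx += x * x;
            sxr += x * r;
          }
        }
        double prec = sxx / sigma2_e + 1.0 / beta_prior_var;
        double mean = (sxr / sigma2_e) / prec;
        double bnew = mean + R::norm_rand() / std::sqrt(prec);
        double shift = bnew - beta[j];
        beta[j] = bnew;
        if (shift != 0.0) {
          for (int i = 0; i < n; ++i) eta[i] += X(i, j) * shift;
        }
      }
    }

    for (int t = 0; t < T; ++t) {
      int L = n_levels[t];
      const IntegerVector &ix = idx[t];
      NumericVector &ut = u[t];
      if (use_likelihood) {
        lev_sum.assign(L, 0.0);
        lev_cnt.assign(L, 0.0);
        for (int i = 0; i < n; ++i) {
          int l = ix[i];
          lev_sum[l] += y[i] - (eta[i] - ut[l]);
          lev_cnt[l] += 1.0;
        }
        shift_store.resize(L);
        for (int l = 0; l < L; ++l) {
          double prec = lev_cnt[l] / sigma2_e + 1.0 / sigma2[t];
          double mean = (lev_sum[l] / sigma2_e) / prec;
          double unew = mean + R::norm_rand() / std::sqrt(prec);
          shift_store[l] = unew - ut[l];
          ut[l] = unew;
        }
        for (int i = 0; i < n; ++i) eta[i] += shift_store[ix[i]];
      } else {
        for (int l = 0; l < L; ++l) {
          ut[l] = R::norm_rand() * std::sqrt(sigma2[t]);
        }
      }
    }

    // sweep moves, as in the Poisson sampler
    if (use_likelihood) {
      for (int t = 0; t < T; ++t) {
        int L = n_levels[t];
        NumericVector &ut = u[t];
        double sum_u = 0.0;
        for (int l = 0; l < L; ++l) sum_u += ut[l];
        double prec = L / sigma2[t] + 1.0 / beta_prior_var;
        double mean = (sum_u / sigma2[t] - beta[0] / beta_prior_var) / prec;
        double s = mean + R::norm_rand() / std::sqrt(prec);
        beta[0] += s;
        for (int l = 0; l < L; ++l) ut[l] -= s;
        const IntegerVector &fm = fmap[t];
        if (fm.size() == L && p > 1) {
          for (int j = 1; j < p; ++j) {
            double su = 0.0;
            int cnt = 0;
            for (int l = 0; l < L; ++l) {
              if (fm[l] == j) { su += ut[l]; ++cnt; }
            }
            if (cnt == 0) continue;
            double pr = cnt / sigma2[t] + 1.0 / beta_prior_var;
            double mn = (su / sigma2[t] - beta[j] / beta_prior_var) / pr;
            double sj = mn + R::norm_rand() / std::sqrt(pr);
            beta[j] += sj;
            for (int l = 0; l < L; ++l) {
              if (fm[l] == j) ut[l] -= sj;
            }
          }
        }
      }
      for (size_t k = 0; k < pairs.size(); ++k) {
        const SweepPair &sp = pairs[k];
        NumericVector &ua = u[sp.a];
        NumericVector &ub = u[sp.b];
        int La = n_levels[sp.a], Lb = n_levels[sp.b];
        acc_s.assign(La, 0.0);
        cnt_s.assign(La, 0.0);
        for (int lb = 0; lb < Lb; ++lb) {
          int la = sp.map[lb];
          acc_s[la] += ub[lb];
          cnt_s[la] += 1.0;
        }
        std::vector<double> shift(La);
        for (int la = 0; la < La; ++la) {
          double pr = 1.0 / sigma2[sp.a] + cnt_s[la] / sigma2[sp.b];
          double mn = (acc_s[la] / sigma2[sp.b] - ua[la] / sigma2[sp.a]) / pr;
          shift[la] = mn + R::norm_rand() / std::sqrt(pr);
          ua[la] += shift[la];
        }
        for (int lb = 0; lb < Lb; ++lb) ub[lb] -= shift[sp.map[lb]];
      }
    }

    for (int t = 0; t < T; ++t) {
      int L = n_levels[t];
      NumericVector &ut = u[t];
      double ss = 0.0;
      for (int l = 0; l < L; ++l) ss += ut[l] * ut[l];
      sigma2[t] = draw_inv_gamma((prior_nu[t] + L) / 2.0,
                                 (prior_nu[t] * prior_V[t] + ss) / 2.0);
    }

    if (use_likelihood) {
      double rss = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = y[i] - eta[i];
        rss += r * r;
      }
      sigma2_e = draw_inv_gamma((resid_nu + n) / 2.0,
                                (resid_nu * resid_V + rss) / 2.0);
    } else {
      sigma2_e = draw_inv_gamma(resid_nu / 2.0, resid_nu * resid_V / 2.0);
    }
    if (!R_finite(sigma2_e)) stop("divergent chain: non-finite residual variance");

    if (iter >= burnin && (iter - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) beta_draws(stored, j) = beta[j];
      for (int t = 0; t < T; ++t) {
        sigma2_draws(stored, t) = sigma2[t];
        NumericMatrix ud = u_draws[t];
        NumericVector &ut = u[t];
        for (int l = 0; l < n_levels[t]; ++l) ud(stored, l) = ut[l];
      }
      sigma2_draws(stored, T) = sigma2_e;
      ++stored;
    }
    if (iter % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["beta"] = beta_draws, _["sigma2"] = sigma2_draws,
                      _["u"] = u_draws);
}
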