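// Metropolis-within-Gibbs sweep for the extended shared component model.
//
// Scalar parameters (intercepts, covariate coefficients, log delta) move by
// random-walk Metropolis; region-indexed components move by sum-preserving
// redistribution proposals (site i gains eps, every other site loses
// eps/(R-1)), which target the sum-to-zero constrained posterior exactly;
// the seven precisions are conjugate Gibbs draws from their gamma full
// conditionals. All randomness flows through R's RNG, so set.seed() on the
// R side makes chains bit-reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double log1pexp_d(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".scm_chain_cpp")]]
List scm_chain_cpp(NumericMatrix O, NumericMatrix N,
                   NumericMatrix X1in, NumericMatrix X2in,
                   IntegerMatrix edges, int n_comp,
                   double pr_shape, double pr_rate, double ld_var,
                   IntegerMatrix miss, NumericVector miss_mean,
                   NumericVector miss_sd,
                   List init,
                   int burn_in, int iterations, int thin,
                   bool adapt_steps, double init_step) {
  const int R = O.ncol();
  const int K = X1in.ncol();
  const int E = edges.nrow();
  const int M = miss.nrow();

  NumericMatrix X1 = clone(X1in);
  NumericMatrix X2 = clone(X2in);

  std::vector<double> alpha = as<std::vector<double> >(init["alpha"]);
  std::vector<double> b1 = as<std::vector<double> >(init["b1"]);
  std::vector<double> b2 = as<std::vector<double> >(init["b2"]);
  double ld = as<double>(init["log_delta"]);
  std::vector<double> ush = as<std::vector<double> >(init["ush"]);
  std::vector<double> ssh = as<std::vector<double> >(init["ssh"]);
  std::vector<double> bind1 = as<std::vector<double> >(init["bind1"]);
  std::vector<double> bind2 = as<std::vector<double> >(init["bind2"]);
  std::vector<double> bspat1 = as<std::vector<double> >(init["bspat1"]);
  std::vector<double> bspat2 = as<std::vector<double> >(init["bspat2"]);
  std::vector<double> gc = as<std::vector<double> >(init["gamma_contrast"]);
  // order: ssh, bspat1, bspat2, gamma, ush, bind1, bind2
  std::vector<double> tau = as<std::vector<double> >(init["tau"]);

  std::vector<double> xm(M);
  for (int m = 0; m < M; m++) {
    int j = miss(m, 0), i = miss(m, 1), k = miss(m, 2);
    xm[m] = (j == 0) ? X1(i, k) : X2(i, k);
  }

  // binomial coefficient constants (for WinBUGS-scale deviances)
  double lcsum = 0.0;
  for (int j = 0; j < 2; j++)
    for (int i = 0; i < R; i++)
      if (N(j, i) > 0) lcsum += Rf_lchoose(N(j, i), O(j, i));

  // --- likelihood helpers ------------------------------------------------
  double ll[2];
  auto cell_lp = [&](int j, int i) -> double {
    double lp = alpha[j];
    if (j == 0) {
      for (int k = 0; k < K; k++) lp += b1[k] * X1(i, k);
    } else {
      for (int k = 0; k < K; k++) lp += b2[k] * X2(i, k);
    }
    double phi = ush[i] + ssh[i];
    double d = std::exp(ld);
    if (j == 0) lp += phi * d + bind1[i] + bspat1[i];
    else        lp += phi / d + gc[i] + bind2[i] + bspat2[i];
    return lp;
  };
  auto cell_ll = [&](int j, int i) -> double {
    if (N(j, i) <= 0) return 0.0;
    double lp = cell_lp(j, i);
    return O(j, i) * lp - N(j, i) * log1pexp_d(lp);
  };
  auto gll = [&](int j) -> double {
    double s = 0.0;
    for (int i = 0; i < R; i++) s += cell_ll(j, i);
    return s;
  };
  auto qform = [&](const std::vector<double>& v) -> double {
    double q = 0.0;
    for (int e = 0; e < E; e++) {
      double d = v[edges(e, 0)] - v[edges(e, 1)];
      q += d * d;
    }
    return q;
  };
  auto ssq = [&](const std::vector<double>& v) -> double {
    double s = 0.0;
    for (size_t i = 0; i < v.size(); i++) s += v[i] * v[i];
    return s;
  };

  ll[0] = gll(0);
  ll[1] = gll(1);
  if (!std::isfinite(ll[0]) || !std::isfinite(ll[1]))
    stop("non-finite log-likelihood at the chain's start state");

  // --- adaptive step bookkeeping -----------------------------------------
  // slots: alpha(2), b1(K), b2(K), ld(1), 7 component vectors, xmiss(M)
  const int SL_ALPHA = 0, SL_B1 = 2, SL_B2 = 2 + K, SL_LD = 2 + 2 * K;
  const int SL_VEC = SL_LD + 1, SL_XM = SL_VEC + 7;
  const int n_slots = SL_XM + M;
  std::vector<double> lstep(n_slots, std::log(init_step));
  std::vector<double> bacc(n_slots, 0.0), btry(n_slots, 0.0);
  std::vector<double> tacc(n_slots, 0.0), ttry(n_slots, 0.0);
  int batch = 0;

  auto decide = [&](int slot, double lacc, bool post) -> bool {
    btry[slot] += 1.0;
    if (post) ttry[slot] += 1.0;
    bool ok = std::log(unif_rand()) < lacc;
    if (ok) {
      bacc[slot] += 1.0;
      if (post) tacc[slot] += 1.0;
    }
    return ok;
  };

  // --- component-vector update (redistribution, sum preserved) -----------
  // gmask: 1 = male likelihood affected, 2 = female, 3 = both
  auto update_vec = [&](std::vector<double>& v, double tauv, bool car,
                        int gmask, int slot, bool post) {
    if (R < 2) return;
    double step = std::exp(lstep[slot]);
    std::vector<double> old(R);
    for (int i = 0; i < R; i++) {
      old = v;
      double eps = step * norm_rand();
      double sub = eps / (R - 1);
      for (int l = 0; l < R; l++) v[l] -= sub;
      v[i] += eps + sub;
      double dpr = car ? -0.5 * tauv * (qform(v) - qform(old))
                       : -0.5 * tauv * (ssq(v) - ssq(old));
      double d = dpr, nll0 = ll[0], nll1 = ll[1];
      if (gmask & 1) { nll0 = gll(0); d += nll0 - ll[0]; }
      if (gmask & 2) { nll1 = gll(1); d += nll1 - ll[1]; }
      if (decide(slot, d, post)) {
        ll[0] = nll0;
        ll[1] = nll1;
      } else {
        v = old;
      }
    }
  };

  const int S = burn_in + iterations;
  const int n_keep = iterations / thin;
  const int P = 3 + 2 * K + 7 * R + 7 + M;
  NumericMatrix draws(n_keep, P);
  NumericMatrix pmat(n_keep, 2 * R);
  NumericVector dev(n_keep);
  int keep_i = 0;

  for (int it = 0; it < S; it++) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    bool post = it >= burn_in;

    // intercepts
    for (int j = 0; j < 2; j++) {
      int slot = SL_ALPHA + j;
      double old = alpha[j];
      alpha[j] += std::exp(lstep[slot]) * norm_rand();
      double nll = gll(j);
      if (decide(slot, nll - ll[j], post)) ll[j] = nll;
      else alpha[j] = old;
    }
    // covariate coefficients (flat priors)
    for (int k = 0; k < K; k++) {
      int slot = SL_B1 + k;
      double old = b1[k];
      b1[k] += std::exp(lstep[slot]) * norm_rand();
      double nll = gll(0);
      if (decide(slot, nll - ll[0], post)) ll[0] = nll;
      else b1[k] = old;
    }
    for (int k = 0; k < K; k++) {
      int slot = SL_B2 + k;
      double old = b2[k];
      b2[k] += std::exp(lstep[slot]) * norm_rand();
      double nll = gll(1);
      if (decide(slot, nll - ll[1], post)) ll[1] = nll;
      else b2[k] = old;
    }
    // log delta: N(0, ld_var) prior, both genders affected
    {
      double old = ld;
      ld += std::exp(lstep[SL_LD]) * norm_rand();
      double nll0 = gll(0), nll1 = gll(1);
      double d = (nll0 - ll[0]) + (nll1 - ll[1]) +
        (old * old - ld * ld) / (2.0 * ld_var);
      if (decide(SL_LD, d, post)) {
        ll[0] = nll0;
        ll[1] = nll1;
      } else ld = old;
    }
    // component vectors
    update_vec(ush, tau[4], false, 3, SL_VEC + 0, post);
    update_vec(ssh, tau[0], true, 3, SL_VEC + 1, post);
    update_vec(bind1, tau[5], false, 1, SL_VEC + 2, post);
    update_vec(bind2, tau[6], false, 2, SL_VEC + 3, post);
    update_vec(bspat1, tau[1], true, 1, SL_VEC + 4, post);
    update_vec(bspat2, tau[2], true, 2, SL_VEC + 5, post);
    update_vec(gc, tau[3], true, 2, SL_VEC + 6, post);
    // imputed covariates: normal prior, single-cell likelihood
    for (int m = 0; m < M; m++) {
      int slot = SL_XM + m;
      int j = miss(m, 0), i = miss(m, 1), k = miss(m, 2);
      double old = xm[m];
      double prop = old + std::exp(lstep[slot]) * norm_rand();
      double ll_old = cell_ll(j, i);
      if (j == 0) X1(i, k) = prop; else X2(i, k) = prop;
      double ll_new = cell_ll(j, i);
      double mu = miss_mean[m], sdv = miss_sd[m];
      double d = ll_new - ll_old +
        (((old - mu) * (old - mu)) - ((prop - mu) * (prop - mu))) /
          (2.0 * sdv * sdv);
      if (decide(slot, d, post)) {
        xm[m] = prop;
        ll[j] += ll_new - ll_old;
      } else {
        if (j == 0) X1(i, k) = old; else X2(i, k) = old;
      }
    }
    // precisions: conjugate gamma full conditionals
    {
      double df_car = 0.5 * (R - n_comp);
      double df_iid = 0.5 * R;
      auto rg = [&](double sh, double rt) {
        double t = R::rgamma(sh, 1.0 / rt);
        if (t < 1e-12) t = 1e-12;
        if (t > 1e12) t = 1e12;
        return t;
      };
      tau[0] = rg(pr_shape + df_car, pr_rate + 0.5 * qform(ssh));
      tau[1] = rg(pr_shape + df_car, pr_rate + 0.5 * qform(bspat1));
      tau[2] = rg(pr_shape + df_car, pr_rate + 0.5 * qform(bspat2));
      tau[3] = rg(pr_shape + df_car, pr_rate + 0.5 * qform(gc));
      tau[4] = rg(pr_shape + df_iid, pr_rate + 0.5 * ssq(ush));
      tau[5] = rg(pr_shape + df_iid, pr_rate + 0.5 * ssq(bind1));
      tau[6] = rg(pr_shape + df_iid, pr_rate + 0.5 * ssq(bind2));
    }

    // step adaptation in batches of 50 during burn-in only
    if (adapt_steps && !post) {
      if (++batch == 50) {
        double gain = std::min(1.0, 10.0 / std::sqrt((it + 1.0) / 50.0));
        for (int s = 0; s < n_slots; s++) {
          if (btry[s] > 0) {
            double rate = bacc[s] / btry[s];
            lstep[s] += gain * (rate - 0.44);
            if (lstep[s] < -12.0) lstep[s] = -12.0;
            if (lstep[s] > 4.0) lstep[s] = 4.0;
          }
          bacc[s] = btry[s] = 0.0;
        }
        batch = 0;
      }
    }

    // record retained draw
    if (post && ((it - burn_in + 1) % thin == 0)) {
      int c = 0;
      draws(keep_i, c++) = alpha[0];
      draws(keep_i, c++) = alpha[1];
      for (int k = 0; k < K; k++) draws(keep_i, c++) = b1[k];
      for (int k = 0; k < K; k++) draws(keep_i, c++) = b2[k];
      draws(keep_i, c++) = ld;
      for (int i = 0; i < R; i++) draws(keep_i, c++) = ush[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = ssh[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = bind1[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = bind2[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = bspat1[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = bspat2[i];
      for (int i = 0; i < R; i++) draws(keep_i, c++) = gc[i];
      for (int t = 0; t < 7; t++) draws(keep_i, c++) = tau[t];
      for (int m = 0; m < M; m++) draws(keep_i, c++) = xm[m];
      for (int j = 0; j < 2; j++)
        for (int i = 0; i < R; i++) {
          double lp = cell_lp(j, i);
          pmat(keep_i, j * R + i) =
            (lp > 0) ? 1.0 / (1.0 + std::exp(-lp))
                     : std::exp(lp) / (1.0 + std::exp(lp));
        }
      dev[keep_i] = -2.0 * (ll[0] + ll[1] + lcsum);
      keep_i++;
    }
  }

  NumericVector acc_rate(n_slots);
  for (int s = 0; s < n_slots; s++)
    acc_rate[s] = (ttry[s] > 0) ? tacc[s] / ttry[s] : NA_REAL;
  NumericVector steps(n_slots);
  for (int s = 0; s < n_slots; s++) steps[s] = std::exp(lstep[s]);

  return List::create(_["draws"] = draws, _["p"] = pmat,
                      _["deviance"] = dev, _["accept"] = acc_rate,
                      _["steps"] = steps);
}
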