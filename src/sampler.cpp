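// Adaptive Metropolis-within-Gibbs sampler for the hierarchical
// spatio-temporal count model:
//   y_ijt ~ NB(mu_jt, n) or ZINB(mu_jt, n, p)
//   log mu_jt = alpha_j + beta_j * x_t + eta_jt + gamma_jt
//   eta_.t ~ N(0, [tau_e (D - lam W)]^-1)  independently per year
//   gamma_j. ~ N(0, [tau_g (Q1(rho) + (cpen/T) 11')]^-1) per stratum
//
// Segment-level counts enter only through per-(stratum, year) sufficient
// statistics (n_zero, n_pos, sum_y) plus a global histogram of positive
// counts, so likelihood work is O(mT) per sweep regardless of the number
// of segments. Internally the intercept is centred (ac_j = a_j + b_j xbar)
// to decorrelate it from the slope; draws are reported on the original
// scale.

#include <Rcpp.h>
using namespace Rcpp;

static inline double logsumexp2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double hi = a > b ? a : b;
  double lo = a > b ? b : a;
  return hi + log1p(std::exp(lo - hi));
}

struct Model {
  int m, T, nc;
  std::vector<int> nzero, npos;
  std::vector<double> sumy;
  std::vector<int> hist_y, hist_cnt;
  double const_lgamma_y1;
  double npos_total;
  // graph (CSR adjacency)
  std::vector<int> adj, adj_ptr;
  std::vector<double> dvec, wev; // row sums; eigenvalues of D^-1/2 W D^-1/2
  double sum_log_d;
  // covariate
  std::vector<double> xc; // centred time covariate
  double xbar;
  bool spatial_on, temporal_on, zinb, lam_est;
  // priors
  double am, aprec, bm, bprec, tau_shape, tau_rate, thm, thprec;
  double rzm, rzsd, lzm, lzsd, pza, pzb, cpen;

  // log-likelihood terms that depend on mu for one cell (constants in mu
  // dropped): used by all mean-changing Metropolis steps
  inline double cell_ll_mu(int c, double lpc, double n, double lp0,
                           double log1mp) const {
    double mu = std::exp(lpc);
    double lnpm = std::log(n + mu);
    double lr = std::log(n) - lnpm;
    double ll = 0.0;
    if (nzero[c]) {
      double lnb0 = n * lr;
      ll += nzero[c] * (zinb ? logsumexp2(lp0, log1mp + lnb0) : lnb0);
    }
    if (npos[c]) ll += npos[c] * n * lr + sumy[c] * (lpc - lnpm);
    return ll;
  }

  // full log-likelihood (all constants included — used for the deviance)
  double loglik_full(const std::vector<double>& lp, double n, double p) const {
    double lp0 = zinb ? std::log(p) : R_NegInf;
    double log1mp = zinb ? std::log1p(-p) : 0.0;
    double lgn = std::lgamma(n);
    double ll = 0.0;
    for (int c = 0; c < nc; ++c) {
      if (!nzero[c] && !npos[c]) continue;
      double mu = std::exp(lp[c]);
      double lnpm = std::log(n + mu);
      double lr = std::log(n) - lnpm;
      if (nzero[c]) {
        double lnb0 = n * lr;
        ll += nzero[c] * (zinb ? logsumexp2(lp0, log1mp + lnb0) : lnb0);
      }
      if (npos[c]) {
        ll += npos[c] * (log1mp + n * lr - lgn) + sumy[c] * (lp[c] - lnpm);
      }
    }
    for (size_t k = 0; k < hist_y.size(); ++k) {
      ll += hist_cnt[k] * std::lgamma(hist_y[k] + n);
    }
    ll -= const_lgamma_y1;
    return ll;
  }

  // unit-tau AR(1) quadratic form of one series + soft-centering penalty
  double quad_gamma_series(const std::vector<double>& g, int j, double rho) const {
    const double* gj = g.data() + (size_t)j * T;
    double q = gj[0] * gj[0] + gj[T - 1] * gj[T - 1];
    double s = gj[0];
    double r2 = rho * rho;
    for (int t = 1; t < T - 1; ++t) { q += (1.0 + r2) * gj[t] * gj[t]; s += gj[t]; }
    if (T > 1) s += gj[T - 1];
    double cross = 0.0;
    for (int t = 0; t < T - 1; ++t) cross += gj[t] * gj[t + 1];
    q -= 2.0 * rho * cross;
    if (T == 1) q = (1.0 - r2) * gj[0] * gj[0];
    q += (cpen / T) * s * s;
    return q;
  }

  // eta' D eta and eta' W eta summed over time slices
  void quad_eta(const std::vector<double>& e, double& qD, double& qW) const {
    qD = 0.0; qW = 0.0;
    for (int j = 0; j < m; ++j) {
      for (int t = 0; t < T; ++t) {
        double ej = e[(size_t)j * T + t];
        qD += dvec[j] * ej * ej;
        double s = 0.0;
        for (int k = adj_ptr[j]; k < adj_ptr[j + 1]; ++k) {
          s += e[(size_t)adj[k] * T + t];
        }
        qW += ej * s;
      }
    }
  }

  // log det(Q1(rho) + (cpen/T) 11') for one series, unit tau
  double logdet_gamma(double rho) const {
    double ld = std::log1p(-rho * rho);
    if (cpen > 0.0) {
      // 1' Q1^{-1} 1 = [T + 2 * sum_k (T-k) rho^k] / (1 - rho^2)
      double s = 0.0, rk = 1.0;
      for (int k = 1; k <= T - 1; ++k) { rk *= rho; s += (T - k) * rk; }
      double u = (T + 2.0 * s) / (1.0 - rho * rho);
      ld += std::log1p((cpen / T) * u);
    }
    return ld;
  }

  double logdet_car(double lam) const {
    double ld = sum_log_d;
    for (int j = 0; j < m; ++j) ld += std::log1p(-lam * wev[j]);
    return ld;
  }
};

static inline double adapt_step(int iter) {
  return std::pow((double)iter + 1.0, -0.6);
}

// [[Rcpp::export(name = ".sampler_run")]]
List sampler_run(List data, List graph, List flags, List priors, List init,
                 int n_warmup, int n_keep, int thin) {
  Model M;
  M.m = as<int>(data["m"]); M.T = as<int>(data["T"]);
  M.nc = M.m * M.T;
  M.nzero = as<std::vector<int> >(data["nzero"]);
  M.npos = as<std::vector<int> >(data["npos"]);
  M.sumy = as<std::vector<double> >(data["sumy"]);
  M.hist_y = as<std::vector<int> >(data["hist_y"]);
  M.hist_cnt = as<std::vector<int> >(data["hist_cnt"]);
  M.const_lgamma_y1 = as<double>(data["const_lgamma_y1"]);
  M.npos_total = 0.0;
  for (int c = 0; c < M.nc; ++c) M.npos_total += M.npos[c];

  M.adj = as<std::vector<int> >(graph["adj"]);       // 0-based
  M.adj_ptr = as<std::vector<int> >(graph["adj_ptr"]);
  M.dvec = as<std::vector<double> >(graph["d"]);
  M.wev = as<std::vector<double> >(graph["wev"]);
  M.sum_log_d = 0.0;
  for (int j = 0; j < M.m; ++j) {
    M.sum_log_d += (M.dvec[j] > 0.0 ? std::log(M.dvec[j]) : 0.0);
  }

  NumericVector x = data["x"];
  M.xbar = mean(x);
  M.xc.resize(M.T);
  for (int t = 0; t < M.T; ++t) M.xc[t] = x[t] - M.xbar;

  M.spatial_on = as<bool>(flags["spatial_on"]);
  M.temporal_on = as<bool>(flags["temporal_on"]);
  M.zinb = as<bool>(flags["zinb"]);
  M.lam_est = as<bool>(flags["lam_est"]);

  M.am = as<double>(priors["alpha_mean"]); M.aprec = as<double>(priors["alpha_prec"]);
  M.bm = as<double>(priors["beta_mean"]); M.bprec = as<double>(priors["beta_prec"]);
  M.tau_shape = as<double>(priors["tau_shape"]); M.tau_rate = as<double>(priors["tau_rate"]);
  M.thm = as<double>(priors["theta_mean"]); M.thprec = as<double>(priors["theta_prec"]);
  M.rzm = as<double>(priors["rho_z_mean"]); M.rzsd = as<double>(priors["rho_z_sd"]);
  M.lzm = as<double>(priors["lam_z_mean"]); M.lzsd = as<double>(priors["lam_z_sd"]);
  M.pza = as<double>(priors["p_zero_a"]); M.pzb = as<double>(priors["p_zero_b"]);
  M.cpen = as<double>(priors["gamma_center_weight"]);

  // state
  std::vector<double> ac = as<std::vector<double> >(init["ac"]);
  std::vector<double> b = as<std::vector<double> >(init["b"]);
  std::vector<double> eta = as<std::vector<double> >(init["eta"]);   // m*T, row-major by stratum
  std::vector<double> gam = as<std::vector<double> >(init["gamma"]);
  double tau_e = as<double>(init["tau_eta"]), tau_g = as<double>(init["tau_gamma"]);
  double rho = as<double>(init["rho"]), lam = as<double>(init["lam"]);
  double p = as<double>(init["p_zero"]), theta = as<double>(init["theta"]);
  double n = std::exp(theta);

  std::vector<double> lp((size_t)M.nc);
  auto refresh_lp = [&](void) {
    for (int j = 0; j < M.m; ++j) {
      for (int t = 0; t < M.T; ++t) {
        size_t c = (size_t)j * M.T + t;
        lp[c] = ac[j] + b[j] * M.xc[t] +
                (M.spatial_on ? eta[c] : 0.0) +
                (M.temporal_on ? gam[c] : 0.0);
      }
    }
  };
  refresh_lp();

  // adaptive proposal log-scales
  std::vector<double> ls_a(M.m, std::log(0.1)), ls_b(M.m, std::log(0.01));
  std::vector<double> ls_ta(M.m, std::log(0.1)), ls_tb(M.m, std::log(0.01)),
                      ls_tc(M.m, std::log(0.1));
  std::vector<double> ls_e, ls_g, ls_sw;
  if (M.spatial_on) ls_e.assign(M.nc, std::log(0.3));
  if (M.temporal_on) ls_g.assign(M.nc, std::log(0.3));
  if (M.spatial_on && M.temporal_on) ls_sw.assign(M.nc, std::log(0.3));
  double ls_r = std::log(0.3), ls_l = std::log(0.5), ls_p = std::log(0.5),
         ls_t = std::log(0.2), ls_se = std::log(0.3), ls_sg = std::log(0.3);
  const double targ = 0.44;

  int n_iter = n_warmup + n_keep * thin;
  NumericMatrix dr_a(n_keep, M.m), dr_b(n_keep, M.m);
  NumericMatrix dr_eta(M.spatial_on ? n_keep : 0, M.spatial_on ? M.nc : 0);
  NumericMatrix dr_gam(M.temporal_on ? n_keep : 0, M.temporal_on ? M.nc : 0);
  NumericMatrix dr_hyp(n_keep, 6); // tau_e, tau_g, rho, lam, p, theta
  NumericVector dr_dev(n_keep);
  std::vector<double> mubar((size_t)M.nc, 0.0);

  RNGScope scope;

  for (int iter = 0; iter < n_iter; ++iter) {
    bool warm = iter < n_warmup;
    double astep = adapt_step(iter);
    double lp0 = M.zinb ? std::log(p) : R_NegInf;
    double log1mp = M.zinb ? std::log1p(-p) : 0.0;

    // ---- stratum intercepts and slopes (centred parameterisation) ----
    for (int j = 0; j < M.m; ++j) {
      { // intercept
        double da = std::exp(ls_a[j]) * norm_rand();
        double dll = 0.0;
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          dll += M.cell_ll_mu(c, lp[c] + da, n, lp0, log1mp) -
                 M.cell_ll_mu(c, lp[c], n, lp0, log1mp);
        }
        double a0 = ac[j] - b[j] * M.xbar, a1 = a0 + da;
        dll += -0.5 * M.aprec * ((a1 - M.am) * (a1 - M.am) -
                                 (a0 - M.am) * (a0 - M.am));
        double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
        if (unif_rand() < acc) {
          ac[j] += da;
          for (int t = 0; t < M.T; ++t) lp[(size_t)j * M.T + t] += da;
        }
        if (warm) ls_a[j] += astep * (acc - targ);
      }
      { // slope
        double db = std::exp(ls_b[j]) * norm_rand();
        double dll = 0.0;
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          dll += M.cell_ll_mu(c, lp[c] + db * M.xc[t], n, lp0, log1mp) -
                 M.cell_ll_mu(c, lp[c], n, lp0, log1mp);
        }
        double b0 = b[j], b1 = b0 + db;
        double a0 = ac[j] - b0 * M.xbar, a1 = ac[j] - b1 * M.xbar;
        dll += -0.5 * M.bprec * ((b1 - M.bm) * (b1 - M.bm) -
                                 (b0 - M.bm) * (b0 - M.bm));
        dll += -0.5 * M.aprec * ((a1 - M.am) * (a1 - M.am) -
                                 (a0 - M.am) * (a0 - M.am));
        double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
        if (unif_rand() < acc) {
          b[j] = b1;
          for (int t = 0; t < M.T; ++t) lp[(size_t)j * M.T + t] += db * M.xc[t];
        }
        if (warm) ls_b[j] += astep * (acc - targ);
      }
    }

    // ---- reattribution moves: shift a constant or a linear-in-time
    //      component between the fixed effects and a latent field. The
    //      linear predictor is unchanged, so these are prior-only MH moves
    //      targeting the intercept/field-mean and slope/field-drift ridges
    //      that defeat single-site updates. ----
    if (M.temporal_on) {
      double r2 = rho * rho;
      for (int j = 0; j < M.m; ++j) {
        double* gj = gam.data() + (size_t)j * M.T;
        { // constant: ac_j += d, gamma_j. -= d
          double d = std::exp(ls_ta[j]) * norm_rand();
          double q0 = M.quad_gamma_series(gam, j, rho);
          for (int t = 0; t < M.T; ++t) gj[t] -= d;
          double q1 = M.quad_gamma_series(gam, j, rho);
          for (int t = 0; t < M.T; ++t) gj[t] += d;
          double a0 = ac[j] - b[j] * M.xbar, a1 = a0 + d;
          double dll = -0.5 * tau_g * (q1 - q0) -
                       0.5 * M.aprec * ((a1 - M.am) * (a1 - M.am) -
                                        (a0 - M.am) * (a0 - M.am));
          double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
          if (unif_rand() < acc) {
            ac[j] += d;
            for (int t = 0; t < M.T; ++t) gj[t] -= d;
          }
          if (warm) ls_ta[j] += astep * (acc - targ);
        }
        { // linear drift: b_j += d, gamma_jt -= d * xc_t
          double d = std::exp(ls_tb[j]) * norm_rand();
          double q0 = M.quad_gamma_series(gam, j, rho);
          for (int t = 0; t < M.T; ++t) gj[t] -= d * M.xc[t];
          double q1 = M.quad_gamma_series(gam, j, rho);
          for (int t = 0; t < M.T; ++t) gj[t] += d * M.xc[t];
          double b0 = b[j], b1 = b0 + d;
          double a0 = ac[j] - b0 * M.xbar, a1 = ac[j] - b1 * M.xbar;
          double dll = -0.5 * tau_g * (q1 - q0) -
                       0.5 * M.bprec * ((b1 - M.bm) * (b1 - M.bm) -
                                        (b0 - M.bm) * (b0 - M.bm)) -
                       0.5 * M.aprec * ((a1 - M.am) * (a1 - M.am) -
                                        (a0 - M.am) * (a0 - M.am));
          double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
          if (unif_rand() < acc) {
            b[j] = b1;
            for (int t = 0; t < M.T; ++t) gj[t] -= d * M.xc[t];
          }
          if (warm) ls_tb[j] += astep * (acc - targ);
        }
      }
      (void)r2;
    }
    if (M.spatial_on) {
      for (int j = 0; j < M.m; ++j) {
        // constant: ac_j += d, eta_j. -= d (one CAR quadratic per slice)
        double d = std::exp(ls_tc[j]) * norm_rand();
        double dq = 0.0;
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          double e0 = eta[c], e1 = e0 - d;
          double nbr = 0.0;
          for (int k = M.adj_ptr[j]; k < M.adj_ptr[j + 1]; ++k) {
            nbr += eta[(size_t)M.adj[k] * M.T + t];
          }
          dq += M.dvec[j] * (e1 * e1 - e0 * e0) + 2.0 * lam * d * nbr;
        }
        double a0 = ac[j] - b[j] * M.xbar, a1 = a0 + d;
        double dll = -0.5 * tau_e * dq -
                     0.5 * M.aprec * ((a1 - M.am) * (a1 - M.am) -
                                      (a0 - M.am) * (a0 - M.am));
        double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
        if (unif_rand() < acc) {
          ac[j] += d;
          for (int t = 0; t < M.T; ++t) eta[(size_t)j * M.T + t] -= d;
        }
        if (warm) ls_tc[j] += astep * (acc - targ);
      }
    }

    // ---- spatial field (single-site, CAR full conditional prior) ----
    if (M.spatial_on) {
      for (int j = 0; j < M.m; ++j) {
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          double de = std::exp(ls_e[c]) * norm_rand();
          double e0 = eta[c], e1 = e0 + de;
          double nbr = 0.0;
          for (int k = M.adj_ptr[j]; k < M.adj_ptr[j + 1]; ++k) {
            nbr += eta[(size_t)M.adj[k] * M.T + t];
          }
          double dpr = -0.5 * tau_e * (M.dvec[j] * (e1 * e1 - e0 * e0) -
                                       2.0 * lam * de * nbr);
          double dll = M.cell_ll_mu(c, lp[c] + de, n, lp0, log1mp) -
                       M.cell_ll_mu(c, lp[c], n, lp0, log1mp) + dpr;
          double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
          if (unif_rand() < acc) { eta[c] = e1; lp[c] += de; }
          if (warm) ls_e[c] += astep * (acc - targ);
        }
      }
    }

    // ---- temporal field (single-site, AR(1) prior + soft centering) ----
    if (M.temporal_on) {
      double r2 = rho * rho;
      for (int j = 0; j < M.m; ++j) {
        double* gj = gam.data() + (size_t)j * M.T;
        double S = 0.0;
        for (int t = 0; t < M.T; ++t) S += gj[t];
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          double dg = std::exp(ls_g[c]) * norm_rand();
          double g0 = gj[t], g1 = g0 + dg;
          double qtt = (t == 0 || t == M.T - 1) ? 1.0 : 1.0 + r2;
          if (M.T == 1) qtt = 1.0 - r2;
          double off = 0.0;
          if (t > 0) off += gj[t - 1];
          if (t < M.T - 1) off += gj[t + 1];
          double S1 = S + dg;
          double dpr = -0.5 * tau_g * (qtt * (g1 * g1 - g0 * g0) -
                                       2.0 * rho * dg * off +
                                       (M.cpen / M.T) * (S1 * S1 - S * S));
          double dll = M.cell_ll_mu(c, lp[c] + dg, n, lp0, log1mp) -
                       M.cell_ll_mu(c, lp[c], n, lp0, log1mp) + dpr;
          double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
          if (unif_rand() < acc) { gj[t] = g1; lp[c] += dg; S = S1; }
          if (warm) ls_g[c] += astep * (acc - targ);
        }
      }
    }

    // ---- prior-only swap between the two fields (fixes the eta+gamma
    //      ridge: likelihood depends only on the sum) ----
    if (M.spatial_on && M.temporal_on) {
      double r2 = rho * rho;
      for (int j = 0; j < M.m; ++j) {
        double* gj = gam.data() + (size_t)j * M.T;
        double S = 0.0;
        for (int t = 0; t < M.T; ++t) S += gj[t];
        for (int t = 0; t < M.T; ++t) {
          size_t c = (size_t)j * M.T + t;
          double d = std::exp(ls_sw[c]) * norm_rand();
          double e0 = eta[c], e1 = e0 + d;
          double g0 = gj[t], g1 = g0 - d;
          double nbr = 0.0;
          for (int k = M.adj_ptr[j]; k < M.adj_ptr[j + 1]; ++k) {
            nbr += eta[(size_t)M.adj[k] * M.T + t];
          }
          double dpr_e = -0.5 * tau_e * (M.dvec[j] * (e1 * e1 - e0 * e0) -
                                         2.0 * lam * d * nbr);
          double qtt = (t == 0 || t == M.T - 1) ? 1.0 : 1.0 + r2;
          if (M.T == 1) qtt = 1.0 - r2;
          double off = 0.0;
          if (t > 0) off += gj[t - 1];
          if (t < M.T - 1) off += gj[t + 1];
          double S1 = S - d;
          double dpr_g = -0.5 * tau_g * (qtt * (g1 * g1 - g0 * g0) +
                                         2.0 * rho * d * off +
                                         (M.cpen / M.T) * (S1 * S1 - S * S));
          double dll = dpr_e + dpr_g; // likelihood unchanged
          double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
          if (unif_rand() < acc) { eta[c] = e1; gj[t] = g1; S = S1; }
          if (warm) ls_sw[c] += astep * (acc - targ);
        }
      }
    }

    // ---- whole-field exchange: propose (eta, tau_e) <-> (gamma, tau_g).
    //      The likelihood only sees eta + gamma, so it is invariant; the
    //      acceptance ratio is the prior ratio of each field evaluated
    //      under the other's correlation structure. Lets chains jump
    //      between the "variance attributed to space" and "variance
    //      attributed to time" modes. ----
    if (M.spatial_on && M.temporal_on) {
      double qDe, qWe, qDg, qWg;
      M.quad_eta(eta, qDe, qWe);
      M.quad_eta(gam, qDg, qWg);
      double qge = 0.0, qgg = 0.0;
      for (int j = 0; j < M.m; ++j) {
        qge += M.quad_gamma_series(eta, j, rho);
        qgg += M.quad_gamma_series(gam, j, rho);
      }
      double dll = -0.5 * (tau_g * (qDg - lam * qWg) + tau_e * qge -
                           tau_e * (qDe - lam * qWe) - tau_g * qgg);
      if (std::isfinite(dll) && unif_rand() < std::exp(dll)) {
        eta.swap(gam);
        std::swap(tau_e, tau_g);
      }
    }

    // ---- joint field/precision rescaling (escapes the funnel where a
    //      field collapses to zero while its precision diverges):
    //      eta' = exp(u) eta, tau' = exp(-2u) tau. The eta-prior term is
    //      scale-invariant; what remains is the Gamma prior on tau and the
    //      likelihood change, plus the exp(mT u) Jacobian which cancels
    //      against the Gaussian log-determinant. ----
    if (M.spatial_on) {
      double u = std::exp(ls_se) * norm_rand();
      double s = std::exp(u);
      double dll = -2.0 * M.tau_shape * u -
                   M.tau_rate * tau_e * (std::exp(-2.0 * u) - 1.0);
      for (int c = 0; c < M.nc; ++c) {
        double nlp = lp[c] + (s - 1.0) * eta[c];
        dll += M.cell_ll_mu(c, nlp, n, lp0, log1mp) -
               M.cell_ll_mu(c, lp[c], n, lp0, log1mp);
      }
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) {
        for (int c = 0; c < M.nc; ++c) {
          lp[c] += (s - 1.0) * eta[c];
          eta[c] *= s;
        }
        tau_e *= std::exp(-2.0 * u);
      }
      if (warm) ls_se += astep * (acc - targ);
    }
    if (M.temporal_on) {
      double u = std::exp(ls_sg) * norm_rand();
      double s = std::exp(u);
      double dll = -2.0 * M.tau_shape * u -
                   M.tau_rate * tau_g * (std::exp(-2.0 * u) - 1.0);
      for (int c = 0; c < M.nc; ++c) {
        double nlp = lp[c] + (s - 1.0) * gam[c];
        dll += M.cell_ll_mu(c, nlp, n, lp0, log1mp) -
               M.cell_ll_mu(c, lp[c], n, lp0, log1mp);
      }
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) {
        for (int c = 0; c < M.nc; ++c) {
          lp[c] += (s - 1.0) * gam[c];
          gam[c] *= s;
        }
        tau_g *= std::exp(-2.0 * u);
      }
      if (warm) ls_sg += astep * (acc - targ);
    }

    // ---- tau_eta: conjugate Gamma ----
    if (M.spatial_on) {
      double qD, qW;
      M.quad_eta(eta, qD, qW);
      double shape = M.tau_shape + 0.5 * M.m * M.T;
      double rate = M.tau_rate + 0.5 * (qD - lam * qW);
      tau_e = R::rgamma(shape, 1.0 / rate);
    }

    // ---- tau_gamma: conjugate Gamma ----
    if (M.temporal_on) {
      double q = 0.0;
      for (int j = 0; j < M.m; ++j) q += M.quad_gamma_series(gam, j, rho);
      double shape = M.tau_shape + 0.5 * M.m * M.T;
      double rate = M.tau_rate + 0.5 * q;
      tau_g = R::rgamma(shape, 1.0 / rate);
    }

    // ---- rho: random walk on z = log((1+rho)/(1-rho)) ----
    if (M.temporal_on) {
      double z0 = std::log((1.0 + rho) / (1.0 - rho));
      double z1 = z0 + std::exp(ls_r) * norm_rand();
      double rho1 = std::tanh(z1 / 2.0);
      double q0 = 0.0, q1 = 0.0;
      for (int j = 0; j < M.m; ++j) {
        q0 += M.quad_gamma_series(gam, j, rho);
        q1 += M.quad_gamma_series(gam, j, rho1);
      }
      double lt0 = 0.5 * M.m * M.logdet_gamma(rho) - 0.5 * tau_g * q0 +
                   R::dnorm(z0, M.rzm, M.rzsd, 1);
      double lt1 = 0.5 * M.m * M.logdet_gamma(rho1) - 0.5 * tau_g * q1 +
                   R::dnorm(z1, M.rzm, M.rzsd, 1);
      double dll = lt1 - lt0;
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) rho = rho1;
      if (warm) ls_r += astep * (acc - targ);
    }

    // ---- lam: random walk on logit(lam) ----
    if (M.spatial_on && M.lam_est) {
      double z0 = std::log(lam / (1.0 - lam));
      double z1 = z0 + std::exp(ls_l) * norm_rand();
      double lam1 = 1.0 / (1.0 + std::exp(-z1));
      double qD, qW;
      M.quad_eta(eta, qD, qW);
      double lt0 = 0.5 * M.T * M.logdet_car(lam) -
                   0.5 * tau_e * (qD - lam * qW) + R::dnorm(z0, M.lzm, M.lzsd, 1);
      double lt1 = 0.5 * M.T * M.logdet_car(lam1) -
                   0.5 * tau_e * (qD - lam1 * qW) + R::dnorm(z1, M.lzm, M.lzsd, 1);
      double dll = lt1 - lt0;
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) lam = lam1;
      if (warm) ls_l += astep * (acc - targ);
    }

    // ---- p_zero: random walk on logit(p) ----
    if (M.zinb) {
      double z0 = std::log(p / (1.0 - p));
      double z1 = z0 + std::exp(ls_p) * norm_rand();
      double p1 = 1.0 / (1.0 + std::exp(-z1));
      auto p_part = [&](double pp) {
        double l0 = std::log(pp), l1 = std::log1p(-pp), s = 0.0;
        for (int c = 0; c < M.nc; ++c) {
          if (M.nzero[c]) {
            double mu = std::exp(lp[c]);
            double lnb0 = n * (std::log(n) - std::log(n + mu));
            s += M.nzero[c] * logsumexp2(l0, l1 + lnb0);
          }
        }
        s += M.npos_total * l1;
        // Beta(a,b) prior on p plus logit Jacobian
        s += M.pza * l0 + M.pzb * l1;
        return s;
      };
      double dll = p_part(p1) - p_part(p);
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) p = p1;
      if (warm) ls_p += astep * (acc - targ);
    }

    // ---- theta = log(n): random walk ----
    {
      double th1 = theta + std::exp(ls_t) * norm_rand();
      double n1 = std::exp(th1);
      double dll = M.loglik_full(lp, n1, p) - M.loglik_full(lp, n, p) -
                   0.5 * M.thprec * ((th1 - M.thm) * (th1 - M.thm) -
                                     (theta - M.thm) * (theta - M.thm));
      double acc = std::isfinite(dll) ? std::min(1.0, std::exp(dll)) : 0.0;
      if (unif_rand() < acc) { theta = th1; n = n1; }
      if (warm) ls_t += astep * (acc - targ);
    }

    // ---- store ----
    if (!warm && ((iter - n_warmup + 1) % thin == 0)) {
      int k = (iter - n_warmup + 1) / thin - 1;
      for (int j = 0; j < M.m; ++j) {
        dr_a(k, j) = ac[j] - b[j] * M.xbar;
        dr_b(k, j) = b[j];
      }
      if (M.spatial_on) for (int c = 0; c < M.nc; ++c) dr_eta(k, c) = eta[c];
      if (M.temporal_on) for (int c = 0; c < M.nc; ++c) dr_gam(k, c) = gam[c];
      dr_hyp(k, 0) = tau_e; dr_hyp(k, 1) = tau_g; dr_hyp(k, 2) = rho;
      dr_hyp(k, 3) = lam; dr_hyp(k, 4) = p; dr_hyp(k, 5) = theta;
      dr_dev[k] = -2.0 * M.loglik_full(lp, n, p);
      for (int c = 0; c < M.nc; ++c) mubar[c] += std::exp(lp[c]) / n_keep;
    }
  }

  return List::create(
    _["alpha"] = dr_a, _["beta"] = dr_b, _["eta"] = dr_eta,
    _["gamma"] = dr_gam, _["hyper"] = dr_hyp, _["deviance"] = dr_dev,
    _["mu_bar"] = NumericVector(mubar.begin(), mubar.end()));
}
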