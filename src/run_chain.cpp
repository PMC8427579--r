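// Full MCMC chain for the hierarchical NB recruitment model, ported from
// the R implementation for speed. The update scheme (documented in
// R/mcmc.R and the package vignette) per iteration:
//   - vectorized single-site Metropolis sweeps over trait-group
//     coefficients (rows partition by group),
//   - joint adaptive (Haario) multivariate proposals per group,
//   - n_inner interleaved sub-sweeps over random effects: single-site
//     sweeps for plot/species effects, a joint adaptive sweep per
//     species, then slice updates of every random-effect scale in
//     centered and non-centered (interweaved) form,
//   - slice update of log(phi),
//   - exact Gibbs draws along likelihood-invariant translation
//     directions (group coefficient vs nested species effects; global
//     intercept vs plot effects).
// Proposal scales and covariances adapt during warmup only. Uses R's RNG
// (seeded from R) so chains are reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Model {
  int n, G, I, J, M, family;
  const double *y, *offset;
  const int *gi, *ii, *ji;     // 0-based
  std::vector<const double*> xcol;
  double beta_sd, sigma_sd, phi_shape, phi_rate;

  // state
  std::vector<double> beta0, beta;       // beta: M x G (column per m)
  std::vector<double> u0p, u0s, us;      // us: M x J
  std::vector<double> sig;               // 2 + M
  double phi;
  std::vector<double> eta, llr;
  std::vector<double> lgyphi, lgy1;
  double c0;

  double &B(int m, int g) { return beta[m * G + g]; }
  double &U(int m, int j) { return us[m * J + j]; }

  void refresh_phi_tables() {
    for (int i = 0; i < n; ++i) lgyphi[i] = R::lgammafn(y[i] + phi);
    c0 = phi * std::log(phi) - R::lgammafn(phi);
  }
  inline double row_ll(double yi, double e, double lg) const {
    if (family == 1) return yi * e - std::exp(e) - lg;
    return 0.0; // unused; NB handled with tables below
  }
  inline double row_ll_nb(int i, double e) const {
    if (family == 1) return y[i] * e - std::exp(e) - lgy1[i];
    return lgyphi[i] - lgy1[i] + c0 + y[i] * e -
           (phi + y[i]) * std::log(std::exp(e) + phi);
  }
  double eta_row(int r) const {
    double e = offset[r] + beta0[gi[r]] + u0p[ii[r]] + u0s[ji[r]];
    for (int m = 0; m < M; ++m) {
      e += (beta[m * G + gi[r]] + us[m * J + ji[r]]) * xcol[m][r];
    }
    return e;
  }
  void refresh_eta_ll() {
    for (int r = 0; r < n; ++r) {
      eta[r] = eta_row(r);
      llr[r] = row_ll_nb(r, eta[r]);
    }
  }
  double sum_ll() const {
    double s = 0;
    for (int r = 0; r < n; ++r) s += llr[r];
    return s;
  }
  double lhalf(double s) const {
    if (s <= 0) return R_NegInf;
    return M_LN2 + R::dnorm(s, 0.0, sigma_sd, 1);
  }
};

// scratch buffers shared by the sweeps
struct Scratch {
  std::vector<double> eta_new, ll_new, d_unit, prop, lu;
  void init(int n, int max_units) {
    eta_new.resize(n); ll_new.resize(n);
    d_unit.resize(max_units); prop.resize(max_units); lu.resize(max_units);
  }
};

// vectorized Metropolis over a coefficient vector whose units partition
// rows. cur has n_units entries; ix is the 0-based row->unit map; xc may
// be nullptr (intercept-like). prior_sd may be a scalar (ps_len == 1).
// Returns per-unit acceptance into acc_count.
void upd_block(Model &mod, Scratch &sc, double *cur, const int *ix,
               const double *xc, const double *steps, const double *prior_sd,
               int ps_len, int n_units, double *acc_count) {
  for (int u = 0; u < n_units; ++u) {
    sc.prop[u] = cur[u] + R::norm_rand() * steps[u];
    sc.d_unit[u] = 0.0;
  }
  for (int r = 0; r < mod.n; ++r) {
    int u = ix[r];
    double delta = sc.prop[u] - cur[u];
    if (xc) delta *= xc[r];
    double e = mod.eta[r] + delta;
    sc.eta_new[r] = e;
    sc.ll_new[r] = mod.row_ll_nb(r, e);
    sc.d_unit[u] += sc.ll_new[r] - mod.llr[r];
  }
  for (int u = 0; u < n_units; ++u) {
    double ps = ps_len == 1 ? prior_sd[0] : prior_sd[u];
    double d = sc.d_unit[u] + R::dnorm(sc.prop[u], 0.0, ps, 1) -
               R::dnorm(cur[u], 0.0, ps, 1);
    sc.lu[u] = (std::log(R::unif_rand()) < d) ? 1.0 : 0.0;
    if (acc_count) acc_count[u] += sc.lu[u];
  }
  for (int r = 0; r < mod.n; ++r) {
    if (sc.lu[ix[r]] > 0.5) {
      mod.eta[r] = sc.eta_new[r];
      mod.llr[r] = sc.ll_new[r];
    }
  }
  for (int u = 0; u < n_units; ++u) {
    if (sc.lu[u] > 0.5) cur[u] = sc.prop[u];
  }
}

// in-place Cholesky (upper) of a d x d matrix stored row-major; returns
// false on failure
bool chol_upper(std::vector<double> &a, int d) {
  for (int i = 0; i < d; ++i) {
    for (int j = i; j < d; ++j) {
      double s = a[i * d + j];
      for (int k = 0; k < i; ++k) s -= a[k * d + i] * a[k * d + j];
      if (i == j) {
        if (s <= 0) return false;
        a[i * d + i] = std::sqrt(s);
      } else {
        a[i * d + j] = s / a[i * d + i];
      }
    }
    for (int j = 0; j < i; ++j) a[i * d + j] = 0.0;
  }
  return true;
}

// adaptive joint proposal bookkeeping for one partition (units x dim)
struct JointAdapt {
  int n_units, d;
  long n_hist = 0;
  std::vector<double> sum, ss, chol, lambda, acc;
  long tries = 0;
  void init(int units, int dim) {
    n_units = units; d = dim;
    sum.assign(units * d, 0.0);
    ss.assign(units * d * d, 0.0);
    chol.assign(units * d * d, 0.0);
    for (int u = 0; u < units; ++u) {
      for (int k = 0; k < d; ++k) chol[u * d * d + k * d + k] = 0.02;
    }
    lambda.assign(units, 1.0);
    acc.assign(units, 0.0);
  }
  void accumulate(const std::vector<double> &cur) {
    ++n_hist;
    for (int u = 0; u < n_units; ++u) {
      const double *c = &cur[u * d];
      double *s = &sum[u * d];
      double *q = &ss[u * d * d];
      for (int a = 0; a < d; ++a) {
        s[a] += c[a];
        for (int b = 0; b < d; ++b) q[a * d + b] += c[a] * c[b];
      }
    }
  }
  void update_chol() {
    if (n_hist < 2L * d + 2L) return;
    std::vector<double> cv(d * d);
    for (int u = 0; u < n_units; ++u) {
      const double *s = &sum[u * d];
      const double *q = &ss[u * d * d];
      for (int a = 0; a < d; ++a) {
        for (int b = 0; b < d; ++b) {
          cv[a * d + b] = (q[a * d + b] - s[a] * s[b] / n_hist) / (n_hist - 1);
        }
        cv[a * d + a] += 1e-6;
      }
      if (chol_upper(cv, d)) {
        std::copy(cv.begin(), cv.end(), chol.begin() + u * d * d);
      }
      // on failure keep the previous factor
    }
  }
};

// one joint Metropolis sweep over all units of a partition; cur is the
// units x d state (unit-major); writers update model columns afterwards
void joint_sweep(Model &mod, Scratch &sc, JointAdapt &ja,
                 std::vector<double> &cur, const int *ix,
                 const std::vector<double> &prior_sd) {
  int d = ja.d, U = ja.n_units;
  double scale = 2.38 / std::sqrt((double)d);
  std::vector<double> prop(cur.size()), z(d);
  for (int u = 0; u < U; ++u) {
    for (int k = 0; k < d; ++k) z[k] = R::norm_rand();
    const double *R_ = &ja.chol[u * d * d];
    for (int k = 0; k < d; ++k) {
      double s = 0;
      for (int a = 0; a <= k; ++a) s += z[a] * R_[a * d + k];
      prop[u * d + k] = cur[u * d + k] + ja.lambda[u] * scale * s;
    }
    sc.d_unit[u] = 0.0;
  }
  for (int r = 0; r < mod.n; ++r) {
    int u = ix[r];
    double delta = prop[u * d] - cur[u * d];
    for (int m = 1; m < d; ++m) {
      delta += (prop[u * d + m] - cur[u * d + m]) * mod.xcol[m - 1][r];
    }
    double e = mod.eta[r] + delta;
    sc.eta_new[r] = e;
    sc.ll_new[r] = mod.row_ll_nb(r, e);
    sc.d_unit[u] += sc.ll_new[r] - mod.llr[r];
  }
  for (int u = 0; u < U; ++u) {
    double dp = 0;
    for (int k = 0; k < d; ++k) {
      dp += R::dnorm(prop[u * d + k], 0.0, prior_sd[k], 1) -
            R::dnorm(cur[u * d + k], 0.0, prior_sd[k], 1);
    }
    double d_ = sc.d_unit[u] + dp;
    sc.lu[u] = (std::log(R::unif_rand()) < d_) ? 1.0 : 0.0;
    ja.acc[u] += sc.lu[u];
  }
  ja.tries += 1;
  for (int r = 0; r < mod.n; ++r) {
    if (sc.lu[ix[r]] > 0.5) {
      mod.eta[r] = sc.eta_new[r];
      mod.llr[r] = sc.ll_new[r];
    }
  }
  for (int u = 0; u < U; ++u) {
    if (sc.lu[u] > 0.5) {
      for (int k = 0; k < d; ++k) cur[u * d + k] = prop[u * d + k];
    }
  }
}

// generic univariate slice sampler (Neal 2003, stepping out + shrinkage)
template <typename F>
double slice1(double x0, F f, double f0, double w = 0.7, int max_step = 8) {
  double ly = f0 - R::exp_rand();
  double lo = x0 - w * R::unif_rand();
  double hi = lo + w;
  for (int k = 0; k < max_step && f(lo) > ly; ++k) lo -= w;
  for (int k = 0; k < max_step && f(hi) > ly; ++k) hi += w;
  for (;;) {
    double x1 = lo + R::unif_rand() * (hi - lo);
    if (f(x1) >= ly) return x1;
    if (x1 < x0) lo = x1; else hi = x1;
  }
}

} // namespace

// [[Rcpp::export]]
NumericMatrix run_chain_cpp(NumericVector y, NumericMatrix X,
                            NumericVector offset, IntegerVector gi1,
                            IntegerVector ii1, IntegerVector ji1,
                            int G, int I, int J, int family,
                            int iter, int warmup, List priors,
                            double init_jitter, int n_inner,
                            int n_joint_g, int joint_start) {
  Model mod;
  mod.n = y.size();
  mod.G = G; mod.I = I; mod.J = J; mod.M = X.ncol();
  mod.family = family;
  mod.y = REAL(y); mod.offset = REAL(offset);
  std::vector<int> gi(mod.n), ii(mod.n), ji(mod.n);
  for (int r = 0; r < mod.n; ++r) {
    gi[r] = gi1[r] - 1; ii[r] = ii1[r] - 1; ji[r] = ji1[r] - 1;
  }
  mod.gi = gi.data(); mod.ii = ii.data(); mod.ji = ji.data();
  mod.xcol.resize(mod.M);
  for (int m = 0; m < mod.M; ++m) mod.xcol[m] = &X(0, m);
  mod.beta_sd = as<double>(priors["beta_sd"]);
  mod.sigma_sd = as<double>(priors["sigma_sd"]);
  mod.phi_shape = as<double>(priors["phi_shape"]);
  mod.phi_rate = as<double>(priors["phi_rate"]);

  int n = mod.n, M = mod.M;
  int nsig = 2 + M;

  // ---- initial state ----
  double ybar = 0, obar = 0;
  for (int r = 0; r < n; ++r) { ybar += mod.y[r]; obar += std::exp(mod.offset[r]); }
  ybar = std::max(ybar / n, 0.01); obar /= n;
  double mu0 = std::log(ybar / obar);
  mod.beta0.assign(G, 0.0);
  for (int g = 0; g < G; ++g) mod.beta0[g] = mu0 + R::norm_rand() * init_jitter;
  mod.beta.assign((size_t)M * G, 0.0);
  for (size_t k = 0; k < mod.beta.size(); ++k) mod.beta[k] = R::norm_rand() * init_jitter;
  mod.u0p.assign(I, 0.0);
  for (int i = 0; i < I; ++i) mod.u0p[i] = R::norm_rand() * 0.01;
  mod.u0s.assign(J, 0.0);
  for (int j = 0; j < J; ++j) mod.u0s[j] = R::norm_rand() * 0.01;
  mod.us.assign((size_t)M * J, 0.0);
  for (size_t k = 0; k < mod.us.size(); ++k) mod.us[k] = R::norm_rand() * 0.01;
  mod.sig.assign(nsig, 0.5);
  mod.phi = std::exp(R::norm_rand() * init_jitter);

  mod.eta.resize(n); mod.llr.resize(n);
  mod.lgyphi.resize(n); mod.lgy1.resize(n);
  for (int r = 0; r < n; ++r) mod.lgy1[r] = R::lgammafn(mod.y[r] + 1.0);
  mod.refresh_phi_tables();
  mod.refresh_eta_ll();

  // species -> group nesting
  std::vector<int> g_of_sp(J, 0);
  std::vector<char> seen(J, 0);
  for (int r = 0; r < n; ++r) {
    if (!seen[ji[r]]) { g_of_sp[ji[r]] = gi[r]; seen[ji[r]] = 1; }
  }
  std::vector<double> n_sp_g(G, 0.0);
  for (int j = 0; j < J; ++j) n_sp_g[g_of_sp[j]] += 1.0;

  // covariates that are constant within each plot (true for site
  // covariates always; for stand covariates when plots have one period)
  std::vector<char> x_plot_const(M, 1);
  std::vector<std::vector<double>> x_of_plot(M, std::vector<double>(I, 0.0));
  {
    std::vector<char> set_i(I);
    for (int m = 0; m < M; ++m) {
      std::fill(set_i.begin(), set_i.end(), 0);
      for (int r = 0; r < n; ++r) {
        int i = ii[r];
        if (!set_i[i]) { x_of_plot[m][i] = mod.xcol[m][r]; set_i[i] = 1; }
        else if (x_of_plot[m][i] != mod.xcol[m][r]) { x_plot_const[m] = 0; break; }
      }
    }
  }

  // ---- adaptation state ----
  int max_units = std::max(std::max(G, I), J);
  Scratch sc; sc.init(n, max_units);
  std::vector<double> st_beta0(G, 0.5), st_beta((size_t)M * G, 0.5);
  std::vector<double> st_u0p(I, 0.5), st_u0s(J, 0.5), st_us((size_t)M * J, 0.5);
  std::vector<double> ac_beta0(G, 0.0), ac_beta((size_t)M * G, 0.0);
  std::vector<double> ac_u0p(I, 0.0), ac_u0s(J, 0.0), ac_us((size_t)M * J, 0.0);
  JointAdapt jg, js;
  int d_c = M + 1;
  jg.init(G, d_c); js.init(J, d_c);
  std::vector<double> cur_g((size_t)G * d_c), cur_s((size_t)J * d_c);
  std::vector<double> prior_g(d_c, mod.beta_sd), prior_s(d_c);
  int batch = 0;

  auto pack_g = [&]() {
    for (int g = 0; g < G; ++g) {
      cur_g[g * d_c] = mod.beta0[g];
      for (int m = 0; m < M; ++m) cur_g[g * d_c + 1 + m] = mod.B(m, g);
    }
  };
  auto unpack_g = [&]() {
    for (int g = 0; g < G; ++g) {
      mod.beta0[g] = cur_g[g * d_c];
      for (int m = 0; m < M; ++m) mod.B(m, g) = cur_g[g * d_c + 1 + m];
    }
  };
  auto pack_s = [&]() {
    for (int j = 0; j < J; ++j) {
      cur_s[j * d_c] = mod.u0s[j];
      for (int m = 0; m < M; ++m) cur_s[j * d_c + 1 + m] = mod.U(m, j);
    }
  };
  auto unpack_s = [&]() {
    for (int j = 0; j < J; ++j) {
      mod.u0s[j] = cur_s[j * d_c];
      for (int m = 0; m < M; ++m) mod.U(m, j) = cur_s[j * d_c + 1 + m];
    }
  };

  int n_keep = iter - warmup;
  int P = G + G * M + I + J + J * M + nsig + (family == 0 ? 1 : 0);
  NumericMatrix draws(n_keep, P);
  std::vector<double> base(n), ll_prop(n);

  for (int it = 1; it <= iter; ++it) {
    if (it % 64 == 0) Rcpp::checkUserInterrupt();
    // -- group coefficients: single-site sweeps then joint sweeps
    upd_block(mod, sc, mod.beta0.data(), mod.gi, nullptr, st_beta0.data(),
              &mod.beta_sd, 1, G, ac_beta0.data());
    for (int m = 0; m < M; ++m) {
      upd_block(mod, sc, &mod.beta[(size_t)m * G], mod.gi, mod.xcol[m],
                &st_beta[(size_t)m * G], &mod.beta_sd, 1, G,
                &ac_beta[(size_t)m * G]);
    }
    if (it > joint_start && M > 0) {
      pack_g();
      for (int rep = 0; rep < n_joint_g; ++rep) {
        joint_sweep(mod, sc, jg, cur_g, mod.gi, prior_g);
      }
      unpack_g();
    }

    // -- interleaved random-effect and scale sub-sweeps
    for (int inner = 0; inner < n_inner; ++inner) {
      upd_block(mod, sc, mod.u0p.data(), mod.ii, nullptr, st_u0p.data(),
                &mod.sig[0], 1, I, ac_u0p.data());
      upd_block(mod, sc, mod.u0s.data(), mod.ji, nullptr, st_u0s.data(),
                &mod.sig[1], 1, J, ac_u0s.data());
      for (int m = 0; m < M; ++m) {
        upd_block(mod, sc, &mod.us[(size_t)m * J], mod.ji, mod.xcol[m],
                  &st_us[(size_t)m * J], &mod.sig[2 + m], 1, J,
                  &ac_us[(size_t)m * J]);
      }
      if (it > joint_start && M > 0) {
        prior_s[0] = mod.sig[1];
        for (int m = 0; m < M; ++m) prior_s[1 + m] = mod.sig[2 + m];
        pack_s();
        joint_sweep(mod, sc, js, cur_s, mod.ji, prior_s);
        unpack_s();
      }
      // centered slice on each log sigma (prior x RE density only)
      for (int k = 0; k < nsig; ++k) {
        const double *u; int len;
        if (k == 0) { u = mod.u0p.data(); len = I; }
        else if (k == 1) { u = mod.u0s.data(); len = J; }
        else { u = &mod.us[(size_t)(k - 2) * J]; len = J; }
        double ssq = 0;
        for (int t = 0; t < len; ++t) ssq += u[t] * u[t];
        auto f_cen = [&](double x) {
          double s = std::exp(x);
          return -len * (std::log(s) + 0.5 * std::log(2.0 * M_PI)) -
                 ssq / (2 * s * s) + mod.lhalf(s) + x;
        };
        double x0 = std::log(mod.sig[k]);
        mod.sig[k] = std::exp(slice1(x0, f_cen, f_cen(x0)));
      }
      // interweaved (non-centered) slice: rescale u with z = u/sigma
      // fixed; target = likelihood x sigma prior (+ Jacobian term)
      for (int k = 0; k < nsig; ++k) {
        for (int r = 0; r < n; ++r) {
          if (k == 0) base[r] = mod.u0p[ii[r]];
          else if (k == 1) base[r] = mod.u0s[ji[r]];
          else base[r] = mod.us[(size_t)(k - 2) * J + ji[r]] * mod.xcol[k - 2][r];
        }
        double lsig0 = std::log(mod.sig[k]);
        double f_at_prop = 0;
        auto f_nc = [&](double x) {
          double ratio = std::exp(x - lsig0);
          double s = 0;
          for (int r = 0; r < n; ++r) {
            ll_prop[r] = mod.row_ll_nb(r, mod.eta[r] + (ratio - 1) * base[r]);
            s += ll_prop[r];
          }
          f_at_prop = s;
          return s + mod.lhalf(std::exp(x)) + x;
        };
        double f0 = mod.sum_ll() + mod.lhalf(mod.sig[k]) + lsig0;
        double x1 = slice1(lsig0, f_nc, f0);
        if (x1 != lsig0) {
          double ratio = std::exp(x1 - lsig0);
          for (int r = 0; r < n; ++r) {
            mod.eta[r] += (ratio - 1) * base[r];
            mod.llr[r] = ll_prop[r];  // last f_nc eval was the accepted point
          }
          if (k == 0) for (int i = 0; i < I; ++i) mod.u0p[i] *= ratio;
          else if (k == 1) for (int j = 0; j < J; ++j) mod.u0s[j] *= ratio;
          else for (int j = 0; j < J; ++j) mod.us[(size_t)(k - 2) * J + j] *= ratio;
          mod.sig[k] = std::exp(x1);
        }
      }
    }

    // -- collapsed scale updates for the species-effect scales: with few
    // species per trait group, the group coefficient and its species
    // effects are separated only by their priors, and sigma controls the
    // split. Sample sigma from the marginal with the likelihood-null
    // translation direction t_g (beta_g -> beta_g - t, u_j -> u_j + t for
    // j in group g) integrated out analytically (the likelihood is
    // invariant along t), then redraw t_g | sigma exactly. Cheap: O(J+G)
    // per evaluation, no likelihood.
    for (int k = 1; k < nsig; ++k) {
      double *u; const double *bvec;
      if (k == 1) { u = mod.u0s.data(); bvec = mod.beta0.data(); }
      else { u = &mod.us[(size_t)(k - 2) * J]; bvec = &mod.beta[(size_t)(k - 2) * G]; }
      std::vector<double> S2(G, 0.0), Q(G, 0.0);
      for (int j = 0; j < J; ++j) {
        S2[g_of_sp[j]] += u[j];
        Q[g_of_sp[j]] += u[j] * u[j];
      }
      double A = 1.0 / (mod.beta_sd * mod.beta_sd);
      auto f_col = [&](double x) {
        double s = std::exp(x), s2 = s * s;
        double tot = mod.lhalf(s) + x;
        for (int g = 0; g < G; ++g) {
          double Bg = n_sp_g[g] / s2;
          double num = A * bvec[g] - S2[g] / s2;
          tot += -n_sp_g[g] * x - Q[g] / (2 * s2) +
                 num * num / (2 * (A + Bg)) - 0.5 * std::log(A + Bg);
        }
        return tot;
      };
      double x0 = std::log(mod.sig[k]);
      double x1 = slice1(x0, f_col, f_col(x0));
      mod.sig[k] = std::exp(x1);
      // redraw the translation t_g | sigma and apply it
      double s2 = mod.sig[k] * mod.sig[k];
      std::vector<double> tg(G);
      for (int g = 0; g < G; ++g) {
        double P = A + n_sp_g[g] / s2;
        double mean = (A * bvec[g] - S2[g] / s2) / P;
        tg[g] = mean + R::norm_rand() / std::sqrt(P);
      }
      for (int g = 0; g < G; ++g) {
        if (k == 1) mod.beta0[g] -= tg[g];
        else mod.B(k - 2, g) -= tg[g];
      }
      for (int j = 0; j < J; ++j) u[j] += tg[g_of_sp[j]];
    }

    // -- dispersion: slice on log(phi)
    if (family == 0) {
      std::vector<double> lgy_prop(n);
      double c0_prop = 0;
      auto f_phi = [&](double x) {
        double ph = std::exp(x);
        c0_prop = ph * x - R::lgammafn(ph);
        double s = 0;
        for (int r = 0; r < n; ++r) {
          lgy_prop[r] = R::lgammafn(mod.y[r] + ph);
          double e = mod.eta[r];
          ll_prop[r] = lgy_prop[r] - mod.lgy1[r] + c0_prop + mod.y[r] * e -
                       (ph + mod.y[r]) * std::log(std::exp(e) + ph);
          s += ll_prop[r];
        }
        return s + R::dgamma(ph, mod.phi_shape, 1.0 / mod.phi_rate, 1) + x;
      };
      double x0 = std::log(mod.phi);
      double f0 = mod.sum_ll() +
                  R::dgamma(mod.phi, mod.phi_shape, 1.0 / mod.phi_rate, 1) + x0;
      double x1 = slice1(x0, f_phi, f0, 0.5);
      if (x1 != x0) {
        mod.phi = std::exp(x1);
        mod.refresh_phi_tables();
        for (int r = 0; r < n; ++r) mod.llr[r] = mod.row_ll_nb(r, mod.eta[r]);
      }
    }

    // -- exact Gibbs translations (likelihood-invariant directions)
    {
      double v = 1.0 / (G / (mod.beta_sd * mod.beta_sd) +
                        I / (mod.sig[0] * mod.sig[0]));
      double sb = 0, su = 0;
      for (int g = 0; g < G; ++g) sb += mod.beta0[g];
      for (int i = 0; i < I; ++i) su += mod.u0p[i];
      double mean = v * (-sb / (mod.beta_sd * mod.beta_sd) +
                         su / (mod.sig[0] * mod.sig[0]));
      double dlt = mean + std::sqrt(v) * R::norm_rand();
      for (int g = 0; g < G; ++g) mod.beta0[g] += dlt;
      for (int i = 0; i < I; ++i) mod.u0p[i] -= dlt;
    }
    {
      double s2 = mod.sig[1] * mod.sig[1];
      std::vector<double> sum_g(G, 0.0);
      for (int j = 0; j < J; ++j) sum_g[g_of_sp[j]] += mod.u0s[j];
      std::vector<double> dlt(G);
      for (int g = 0; g < G; ++g) {
        double v = 1.0 / (1.0 / (mod.beta_sd * mod.beta_sd) + n_sp_g[g] / s2);
        double mean = v * (-mod.beta0[g] / (mod.beta_sd * mod.beta_sd) +
                           sum_g[g] / s2);
        dlt[g] = mean + std::sqrt(v) * R::norm_rand();
        mod.beta0[g] += dlt[g];
      }
      for (int j = 0; j < J; ++j) mod.u0s[j] -= dlt[g_of_sp[j]];
    }
    for (int m = 0; m < M; ++m) {
      double s2 = mod.sig[2 + m] * mod.sig[2 + m];
      std::vector<double> sum_g(G, 0.0);
      for (int j = 0; j < J; ++j) sum_g[g_of_sp[j]] += mod.U(m, j);
      std::vector<double> dlt(G);
      for (int g = 0; g < G; ++g) {
        double v = 1.0 / (1.0 / (mod.beta_sd * mod.beta_sd) + n_sp_g[g] / s2);
        double mean = v * (-mod.B(m, g) / (mod.beta_sd * mod.beta_sd) +
                           sum_g[g] / s2);
        dlt[g] = mean + std::sqrt(v) * R::norm_rand();
        mod.B(m, g) += dlt[g];
      }
      for (int j = 0; j < J; ++j) mod.U(m, j) -= dlt[g_of_sp[j]];
    }

    // -- translation between a covariate's coefficients (all groups) and
    // the plot intercepts: when x^(m) is constant within each plot,
    // shifting every beta_g^(m) by delta and subtracting delta * x_i from
    // each plot effect leaves eta unchanged (plot-level covariates are
    // partially confounded with plot intercepts); the conditional of the
    // shift is Gaussian
    for (int m = 0; m < M; ++m) {
      if (!x_plot_const[m]) continue;
      double s2 = mod.sig[0] * mod.sig[0];
      double sb2 = mod.beta_sd * mod.beta_sd;
      double sxx = 0, sux = 0, sbm = 0;
      for (int i = 0; i < I; ++i) {
        sxx += x_of_plot[m][i] * x_of_plot[m][i];
        sux += mod.u0p[i] * x_of_plot[m][i];
      }
      for (int g = 0; g < G; ++g) sbm += mod.B(m, g);
      double v = 1.0 / (G / sb2 + sxx / s2);
      double mean = v * (-sbm / sb2 + sux / s2);
      double dlt = mean + std::sqrt(v) * R::norm_rand();
      for (int g = 0; g < G; ++g) mod.B(m, g) += dlt;
      for (int i = 0; i < I; ++i) mod.u0p[i] -= dlt * x_of_plot[m][i];
    }

    // -- accumulate joint-proposal covariances (warmup only)
    if (it <= warmup && it > 50 && M > 0) {
      pack_g(); pack_s();
      jg.accumulate(cur_g);
      js.accumulate(cur_s);
    }

    // -- adaptation (warmup only, batches of 50)
    if (it <= warmup && it % 50 == 0) {
      if (M > 0) { jg.update_chol(); js.update_chol(); }
      ++batch;
      double gain = std::min(0.1, 1.0 / std::sqrt((double)batch));
      if (M > 0 && it > joint_start) {
        double gt = (double)jg.tries;
        if (gt > 0) {
          for (int g = 0; g < G; ++g) {
            jg.lambda[g] *= std::exp(jg.acc[g] / gt > 0.23 ? gain : -gain);
            jg.acc[g] = 0;
          }
          jg.tries = 0;
        }
        double st = (double)js.tries;
        if (st > 0) {
          for (int j = 0; j < J; ++j) {
            js.lambda[j] *= std::exp(js.acc[j] / st > 0.23 ? gain : -gain);
            js.acc[j] = 0;
          }
          js.tries = 0;
        }
      }
      auto tune = [&](std::vector<double> &st_, std::vector<double> &ac_,
                      double tries) {
        for (size_t k = 0; k < st_.size(); ++k) {
          st_[k] *= std::exp(ac_[k] / tries > 0.44 ? gain : -gain);
          ac_[k] = 0;
        }
      };
      tune(st_beta0, ac_beta0, 50.0);
      tune(st_beta, ac_beta, 50.0);
      tune(st_u0p, ac_u0p, 50.0 * n_inner);
      tune(st_u0s, ac_u0s, 50.0 * n_inner);
      tune(st_us, ac_us, 50.0 * n_inner);
    }

    // -- record
    if (it > warmup) {
      int row = it - warmup - 1, col = 0;
      for (int g = 0; g < G; ++g) draws(row, col++) = mod.beta0[g];
      for (int m = 0; m < M; ++m) {
        for (int g = 0; g < G; ++g) draws(row, col++) = mod.B(m, g);
      }
      for (int i = 0; i < I; ++i) draws(row, col++) = mod.u0p[i];
      for (int j = 0; j < J; ++j) draws(row, col++) = mod.u0s[j];
      for (int m = 0; m < M; ++m) {
        for (int j = 0; j < J; ++j) draws(row, col++) = mod.U(m, j);
      }
      for (int k = 0; k < nsig; ++k) draws(row, col++) = mod.sig[k];
      if (family == 0) draws(row, col++) = mod.phi;
    }
  }
  return draws;
}
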