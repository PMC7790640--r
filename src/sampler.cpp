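// Joint CJS + growth + fecundity likelihood and adaptive blockwise
// random-walk Metropolis sampler. Parameter vector theta has 31 entries in
// the package's canonical order; theta[30] holds log(egg_var).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();
static const double VAR_FLOOR = 0.1;

struct CmrData {
  // survey layout
  std::vector<int> site_nocc, site_off;
  std::vector<double> times;   // concatenated per site
  std::vector<int> seas;       // 1 or 2, concatenated per site
  // individuals
  std::vector<int> ind_site, ind_first, ind_det_off;
  std::vector<int> det;        // concatenated detection histories
  std::vector<double> x1;      // -1 when absent
  std::vector<int> has_growth, latent; // latent: index into latent vector or -1
  std::vector<double> x2_obs;  // -1 when latent/absent
  // eggs
  std::vector<double> egg_size, egg_count;
  std::vector<int> egg_site, egg_season;
  int n_ind;
};

static CmrData unpack(const List& d) {
  CmrData c;
  c.site_nocc = as<std::vector<int>>(d["site_nocc"]);
  c.site_off = as<std::vector<int>>(d["site_off"]);
  c.times = as<std::vector<double>>(d["times"]);
  c.seas = as<std::vector<int>>(d["seas"]);
  c.ind_site = as<std::vector<int>>(d["ind_site"]);
  c.ind_first = as<std::vector<int>>(d["ind_first"]);
  c.ind_det_off = as<std::vector<int>>(d["ind_det_off"]);
  c.det = as<std::vector<int>>(d["det"]);
  c.x1 = as<std::vector<double>>(d["x1"]);
  c.has_growth = as<std::vector<int>>(d["has_growth"]);
  c.latent = as<std::vector<int>>(d["latent"]);
  c.x2_obs = as<std::vector<double>>(d["x2_obs"]);
  c.egg_size = as<std::vector<double>>(d["egg_size"]);
  c.egg_count = as<std::vector<double>>(d["egg_count"]);
  c.egg_site = as<std::vector<int>>(d["egg_site"]);
  c.egg_season = as<std::vector<int>>(d["egg_season"]);
  c.n_ind = (int)c.ind_site.size();
  return c;
}

// ---- effective coefficients (site 0-based, season 1/2) ----
static inline double haz_int(const double* t, int s, int se) {
  return t[18] + (s == 1 ? t[22] : s == 2 ? t[23] : 0.0) + (se == 2 ? t[20] : 0.0);
}
static inline double haz_slp(const double* t, int s, int se) {
  (void)s; return t[19] + (se == 2 ? t[21] : 0.0);
}
static inline double rec_int(const double* t, int s, int se) {
  return t[24] + (s == 1 ? t[28] : s == 2 ? t[29] : 0.0) + (se == 2 ? t[26] : 0.0);
}
static inline double rec_slp(const double* t, int s, int se) {
  (void)s; return t[25] + (se == 2 ? t[27] : 0.0);
}
static inline double gK(const double* t, int s) {
  return t[0] + (s == 1 ? t[2] : s == 2 ? t[3] : 0.0);
}
static inline double gL(const double* t, int s) {
  return t[1] + (s == 1 ? t[4] : s == 2 ? t[5] : 0.0);
}
static inline double gv(const double* t, int s, double x) {
  double a = t[6] + (s == 1 ? t[8] : s == 2 ? t[9] : 0.0);
  double b = t[7] + (s == 1 ? t[10] : s == 2 ? t[11] : 0.0);
  double v = a + b * x;
  return v > VAR_FLOOR ? v : VAR_FLOOR;
}
static inline double egg_mu(const double* t, int s, int se, double x) {
  double c = t[12] + (s == 1 ? t[16] : s == 2 ? t[17] : 0.0) + (se == 2 ? t[14] : 0.0);
  double d = t[13] + (se == 2 ? t[15] : 0.0);
  return c + d * x;
}
static inline double inv_logit(double z) { return 1.0 / (1.0 + std::exp(-z)); }
static inline double sm(double e, double f, double x) {
  return std::exp(-std::exp(e + f * x));
}

// ---- likelihood components ----
static double growth_ll(const CmrData& c, const double* t, const std::vector<double>& x2) {
  double ll = 0.0;
  for (int i = 0; i < c.n_ind; ++i) {
    if (!c.has_growth[i]) continue;
    int s = c.ind_site[i];
    double K = gK(t, s), L = gL(t, s);
    if (K <= 0.0 || L <= 0.0) return NEG_INF;
    double m = std::exp(-K) * c.x1[i] + L * (1.0 - std::exp(-K));
    double v = gv(t, s, c.x1[i]);
    double r = x2[i] - m;
    ll += -0.5 * std::log(2.0 * M_PI * v) - r * r / (2.0 * v);
  }
  return ll;
}

static double egg_ll(const CmrData& c, const double* t) {
  double s2 = std::exp(t[30]);
  double ll = 0.0;
  for (size_t k = 0; k < c.egg_size.size(); ++k) {
    double mu = egg_mu(t, c.egg_site[k], c.egg_season[k], c.egg_size[k]);
    double r = c.egg_count[k] - mu;
    ll += -0.5 * std::log(2.0 * M_PI * s2) - r * r / (2.0 * s2);
  }
  return ll;
}

static double cjs_ll_ind(const CmrData& c, const double* t, int i,
                         const std::vector<double>& x2) {
  int s = c.ind_site[i];
  int T = c.site_nocc[s];
  const double* tm = &c.times[c.site_off[s]];
  const int* se = &c.seas[c.site_off[s]];
  const int* y = &c.det[c.ind_det_off[i]];
  int first = c.ind_first[i];
  int last = first;
  for (int j = first; j < T; ++j) if (y[j]) last = j;
  double ll = 0.0;
  // sizes per occasion
  auto xo = [&](int j) { return se[j] == 1 ? c.x1[i] : x2[i]; };
  auto phi = [&](int j) {
    double e = haz_int(t, s, se[j]), f = haz_slp(t, s, se[j]);
    return std::pow(sm(e, f, xo(j)), tm[j + 1] - tm[j]);
  };
  auto pdet = [&](int j) {
    return inv_logit(rec_int(t, s, se[j]) + rec_slp(t, s, se[j]) * xo(j));
  };
  for (int j = first; j < last; ++j) {
    double ph = phi(j), p = pdet(j + 1);
    if (ph <= 0.0) return NEG_INF;
    ll += std::log(ph) + (y[j + 1] ? std::log(p) : std::log1p(-p));
  }
  double chi = 1.0;
  for (int j = T - 2; j >= last; --j) {
    double ph = phi(j), p = pdet(j + 1);
    chi = (1.0 - ph) + ph * (1.0 - p) * chi;
  }
  if (chi <= 0.0) return NEG_INF;
  return ll + std::log(chi);
}

// log chi part only: the terms of one individual's CJS likelihood that
// depend on its season-2 size when it was never detected in season 2
static double cjs_logchi_ind(const CmrData& c, const double* t, int i,
                             const std::vector<double>& x2) {
  int s = c.ind_site[i];
  int T = c.site_nocc[s];
  const double* tm = &c.times[c.site_off[s]];
  const int* se = &c.seas[c.site_off[s]];
  const int* y = &c.det[c.ind_det_off[i]];
  int first = c.ind_first[i];
  int last = first;
  for (int j = first; j < T; ++j) if (y[j]) last = j;
  auto xo = [&](int j) { return se[j] == 1 ? c.x1[i] : x2[i]; };
  double chi = 1.0;
  for (int j = T - 2; j >= last; --j) {
    double e = haz_int(t, s, se[j]), f = haz_slp(t, s, se[j]);
    double ph = std::pow(sm(e, f, xo(j)), tm[j + 1] - tm[j]);
    double p = inv_logit(rec_int(t, s, se[j + 1]) + rec_slp(t, s, se[j + 1]) * xo(j + 1));
    chi = (1.0 - ph) + ph * (1.0 - p) * chi;
  }
  return chi > 0.0 ? std::log(chi) : NEG_INF;
}

static double cjs_ll(const CmrData& c, const double* t, const std::vector<double>& x2) {
  double ll = 0.0;
  for (int i = 0; i < c.n_ind; ++i) {
    ll += cjs_ll_ind(c, t, i, x2);
    if (ll == NEG_INF) return NEG_INF;
  }
  return ll;
}

static double prior_block(const double* t, const std::vector<int>& idx) {
  double lp = 0.0;
  for (int k : idx) {
    if (k < 30) {
      lp += -0.5 * t[k] * t[k] / 100.0;  // N(0, 10^2), constants dropped
    } else {
      double sig = std::exp(0.5 * t[30]);
      if (sig >= 20.0) return NEG_INF;
      lp += 0.5 * t[30];  // uniform(0,20) on SD, Jacobian to log-variance
    }
  }
  return lp;
}

// [[Rcpp::export(name = ".joint_loglik_cpp")]]
double joint_loglik_cpp(List data, NumericVector theta, NumericVector latent_x2) {
  CmrData c = unpack(data);
  const double* t = theta.begin();
  std::vector<double> x2(c.n_ind);
  for (int i = 0; i < c.n_ind; ++i) {
    x2[i] = c.latent[i] >= 0 ? latent_x2[c.latent[i]] : c.x2_obs[i];
  }
  double g = growth_ll(c, t, x2);
  if (g == NEG_INF) return NEG_INF;
  return cjs_ll(c, t, x2) + g + egg_ll(c, t);
}

// lower-triangular Cholesky for small dense matrices
static bool chol_small(std::vector<double>& A, int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int k = 0; k < j; ++k) s -= A[j * d + k] * A[j * d + k];
    if (s <= 0.0) return false;
    A[j * d + j] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double v = A[i * d + j];
      for (int k = 0; k < j; ++k) v -= A[i * d + k] * A[j * d + k];
      A[i * d + j] = v / A[j * d + j];
    }
    for (int k = j + 1; k < d; ++k) A[j * d + k] = 0.0;
  }
  return true;
}

// [[Rcpp::export(name = ".run_mcmc_cpp")]]
List run_mcmc_cpp(List data, NumericVector theta0, NumericVector latent0,
                  int n_iter, int n_burn, int thin, NumericVector init_sd) {
  CmrData c = unpack(data);
  const int P = 31;
  std::vector<double> th(theta0.begin(), theta0.end());
  int n_lat = latent0.size();
  std::vector<double> lat(latent0.begin(), latent0.end());
  std::vector<double> x2(c.n_ind);
  for (int i = 0; i < c.n_ind; ++i)
    x2[i] = c.latent[i] >= 0 ? lat[c.latent[i]] : c.x2_obs[i];

  std::vector<std::vector<int>> blocks = {
    {0, 1, 2, 3, 4, 5},          // growth mean
    {6, 7, 8, 9, 10, 11},        // growth variance
    {12, 13, 14, 15, 16, 17, 30},// eggs
    {18, 19, 20, 21, 22, 23},    // hazard
    {24, 25, 26, 27, 28, 29}     // recapture
  };
  const int B = (int)blocks.size();
  // 0/1: growth loglik; 2: eggs; 3/4: cjs
  auto block_ll = [&](int b) {
    if (b <= 1) return growth_ll(c, th.data(), x2);
    if (b == 2) return egg_ll(c, th.data());
    return cjs_ll(c, th.data(), x2);
  };

  // adaptation state
  std::vector<std::vector<double>> mean(B), cov(B), chol(B);
  std::vector<double> scale(B), acc(B, 0.0), tries(B, 0.0);
  std::vector<long> nadapt(B, 0);
  for (int b = 0; b < B; ++b) {
    int d = (int)blocks[b].size();
    mean[b].assign(d, 0.0);
    cov[b].assign(d * d, 0.0);
    chol[b].assign(d * d, 0.0);
    for (int j = 0; j < d; ++j) chol[b][j * d + j] = init_sd[blocks[b][j]];
    scale[b] = 1.0;
  }
  double lat_acc = 0.0, lat_tries = 0.0;

  double cur_growth = growth_ll(c, th.data(), x2);
  double cur_eggs = egg_ll(c, th.data());
  double cur_cjs = cjs_ll(c, th.data(), x2);
  if (cur_growth == NEG_INF || cur_cjs == NEG_INF)
    stop("initial values have zero likelihood");

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix draws(n_keep, P);
  int kept = 0;
  RNGScope rng;
  std::vector<double> prop(P), z;

  for (int it = 1; it <= n_iter; ++it) {
    for (int b = 0; b < B; ++b) {
      int d = (int)blocks[b].size();
      z.resize(d);
      for (int j = 0; j < d; ++j) z[j] = R::norm_rand();
      std::copy(th.begin(), th.end(), prop.begin());
      for (int i2 = 0; i2 < d; ++i2) {
        double step = 0.0;
        for (int j = 0; j <= i2; ++j) step += chol[b][i2 * d + j] * z[j];
        prop[blocks[b][i2]] += scale[b] * step;
      }
      double lp0 = prior_block(th.data(), blocks[b]);
      double lp1 = prior_block(prop.data(), blocks[b]);
      double cur = (b <= 1) ? cur_growth : (b == 2) ? cur_eggs : cur_cjs;
      double newll = NEG_INF;
      if (lp1 > NEG_INF) {
        std::swap(th, prop);
        newll = block_ll(b);
        std::swap(th, prop);
      }
      tries[b] += 1.0;
      if (newll > NEG_INF &&
          std::log(R::unif_rand()) < (newll + lp1) - (cur + lp0)) {
        std::swap(th, prop);
        if (b <= 1) cur_growth = newll;
        else if (b == 2) cur_eggs = newll;
        else cur_cjs = newll;
        acc[b] += 1.0;
      }
      // running moments for covariance adaptation (burn-in only)
      if (it <= n_burn) {
        nadapt[b]++;
        double w = 1.0 / nadapt[b];
        std::vector<double> dv(d);
        for (int j = 0; j < d; ++j) {
          dv[j] = th[blocks[b][j]] - mean[b][j];
          mean[b][j] += w * dv[j];
        }
        for (int i2 = 0; i2 < d; ++i2)
          for (int j = 0; j < d; ++j)
            cov[b][i2 * d + j] += w * (dv[i2] * dv[j] * (1.0 - w) - cov[b][i2 * d + j]);
      }
    }
    // latent season-2 sizes: independence proposal from the growth
    // conditional N(m, v); the Hastings ratio then reduces to the chi part
    // of the individual's CJS likelihood (everything else is free of x2 for
    // an animal never detected in season 2)
    for (int i = 0; i < c.n_ind; ++i) {
      if (c.latent[i] < 0) continue;
      int s = c.ind_site[i];
      double K = gK(th.data(), s), L = gL(th.data(), s);
      double m = std::exp(-K) * c.x1[i] + L * (1.0 - std::exp(-K));
      double v = gv(th.data(), s, c.x1[i]);
      double x_old = x2[i];
      double x_new = m + std::sqrt(v) * R::norm_rand();
      lat_tries += 1.0;
      if (x_new < 5.0 || x_new > 80.0) continue;
      double chi_old = cjs_logchi_ind(c, th.data(), i, x2);
      x2[i] = x_new;
      double chi_new = cjs_logchi_ind(c, th.data(), i, x2);
      if (chi_new > NEG_INF && std::log(R::unif_rand()) < chi_new - chi_old) {
        lat[c.latent[i]] = x_new;
        lat_acc += 1.0;
        cur_cjs += chi_new - chi_old;
        double r_old = x_old - m, r_new = x_new - m;
        cur_growth += (r_old * r_old - r_new * r_new) / (2.0 * v);
      } else {
        x2[i] = x_old;
      }
    }
    // guard against float drift in the incrementally maintained totals
    if (it % 1000 == 0) {
      cur_cjs = cjs_ll(c, th.data(), x2);
      cur_growth = growth_ll(c, th.data(), x2);
    }

    // adapt proposal scales and covariances during burn-in
    if (it <= n_burn && it % 100 == 0) {
      for (int b = 0; b < B; ++b) {
        double ar = acc[b] / std::max(tries[b], 1.0);
        scale[b] *= std::exp(0.66 * (ar - 0.25));
        acc[b] = tries[b] = 0.0;
        if (it >= 500) {
          int d = (int)blocks[b].size();
          std::vector<double> A(cov[b]);
          double mult = 5.6644 / d;  // 2.38^2 / d
          for (int j = 0; j < d * d; ++j) A[j] *= mult;
          for (int j = 0; j < d; ++j) A[j * d + j] += 1e-8;
          if (chol_small(A, d)) { chol[b] = A; scale[b] = 1.0; }
        }
      }
    }

    if (it > n_burn && (it - n_burn) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < P; ++j) draws(kept, j) = th[j];
      ++kept;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["draws"] = draws,
                      _["latent"] = NumericVector(lat.begin(), lat.end()));
}
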