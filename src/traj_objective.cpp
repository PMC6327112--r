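#include <Rcpp.h>
using namespace Rcpp;

// Zero-inflated sigmoid factor model: log posterior and gradient.
// Mirrors the reference R implementation (traj_objective) exactly; the two
// are cross-checked in the test suite.
//
// Parameter layout: u (n cells), then per gene (a, k, v, ls) column-major,
// then beta0, beta1. Transforms: t = sigmoid(u), t0 = sigmoid(v),
// mu0 = softplus(a), sigma = exp(ls).

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double log_sigmoid(double x) {
  // log(1/(1+exp(-x))) computed stably
  return x < -30.0 ? x : -std::log1p(std::exp(-x));
}

static inline double softplus(double x) {
  return x > 30.0 ? x : std::log1p(std::exp(x));
}

// [[Rcpp::export(name = ".traj_objective_cpp")]]
List traj_objective_cpp(NumericVector par, NumericMatrix X, LogicalMatrix Z,
                        double t_sd, double t0_sd, double k_sd,
                        double mu0_sd, double beta_sd,
                        bool dropout, bool optimize_beta, bool grad) {
  const int g = X.nrow(), n = X.ncol();
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<double> t(n), gu(n, 0.0);
  for (int j = 0; j < n; ++j) t[j] = sigmoid(par[j]);
  std::vector<double> mu0(g), k(g), t0(g), ls(g), sigma(g);
  for (int i = 0; i < g; ++i) {
    mu0[i] = softplus(par[n + i]);
    k[i] = par[n + g + i];
    t0[i] = sigmoid(par[n + 2 * g + i]);
    ls[i] = par[n + 3 * g + i];
    sigma[i] = std::exp(ls[i]);
  }
  const double beta0 = par[n + 4 * g];
  const double beta1 = par[n + 4 * g + 1];

  double ll = 0.0;
  std::vector<double> g_mu0(g, 0.0), g_k(g, 0.0), g_t0(g, 0.0), g_ls(g, 0.0);
  double g_b0 = 0.0, g_b1 = 0.0;

  for (int i = 0; i < g; ++i) {
    const double two_mu0 = 2.0 * mu0[i];
    const double inv_s2 = 1.0 / (sigma[i] * sigma[i]);
    double acc_mu0 = 0.0, acc_k = 0.0, acc_t0 = 0.0, acc_ls = 0.0;
    for (int j = 0; j < n; ++j) {
      const double d = t[j] - t0[i];
      const double s = sigmoid(k[i] * d);
      const double M = two_mu0 * s;
      const double x = X(i, j);
      const bool z = Z(i, j);
      double G = 0.0;               // dL/dM
      if (dropout) {
        const double eta = beta0 + beta1 * M;
        const double pd = sigmoid(eta);
        if (z) {
          ll += log_sigmoid(eta);
          G = (1.0 - pd) * beta1;
          if (optimize_beta) { g_b0 += 1.0 - pd; g_b1 += (1.0 - pd) * M; }
        } else {
          const double R = x - M;
          ll += log_sigmoid(-eta) - 0.5 * LOG2PI - ls[i] - 0.5 * R * R * inv_s2;
          G = -pd * beta1 + R * inv_s2;
          acc_ls += -1.0 + R * R * inv_s2;
          if (optimize_beta) { g_b0 -= pd; g_b1 -= pd * M; }
        }
      } else {
        const double R = x - M;
        ll += -0.5 * LOG2PI - ls[i] - 0.5 * R * R * inv_s2;
        G = R * inv_s2;
        acc_ls += -1.0 + R * R * inv_s2;
      }
      if (grad) {
        const double ss1 = s * (1.0 - s);
        const double common = two_mu0 * k[i] * ss1;
        acc_mu0 += G * 2.0 * s;
        acc_k += G * two_mu0 * ss1 * d;
        acc_t0 -= G * common;
        gu[j] += G * common;
      }
    }
    g_mu0[i] = acc_mu0;
    g_k[i] = acc_k;
    g_t0[i] = acc_t0;
    g_ls[i] = acc_ls;
  }

  // priors
  double lp = ll;
  for (int j = 0; j < n; ++j)
    lp -= (t[j] - 0.5) * (t[j] - 0.5) / (2.0 * t_sd * t_sd);
  for (int i = 0; i < g; ++i) {
    lp -= (t0[i] - 0.5) * (t0[i] - 0.5) / (2.0 * t0_sd * t0_sd);
    lp -= k[i] * k[i] / (2.0 * k_sd * k_sd);
    lp -= mu0[i] * mu0[i] / (2.0 * mu0_sd * mu0_sd);
  }
  if (dropout && optimize_beta)
    lp -= (beta0 * beta0 + beta1 * beta1) / (2.0 * beta_sd * beta_sd);

  if (!grad) return List::create(_["value"] = lp);

  NumericVector gr(n + 4 * g + 2);
  for (int j = 0; j < n; ++j) {
    const double gt = gu[j] - (t[j] - 0.5) / (t_sd * t_sd);
    gr[j] = gt * t[j] * (1.0 - t[j]);
  }
  for (int i = 0; i < g; ++i) {
    const double gm = g_mu0[i] - mu0[i] / (mu0_sd * mu0_sd);
    gr[n + i] = gm * sigmoid(par[n + i]);           // softplus'
    gr[n + g + i] = g_k[i] - k[i] / (k_sd * k_sd);
    const double gt0 = g_t0[i] - (t0[i] - 0.5) / (t0_sd * t0_sd);
    gr[n + 2 * g + i] = gt0 * t0[i] * (1.0 - t0[i]);
    gr[n + 3 * g + i] = g_ls[i];
  }
  if (dropout && optimize_beta) {
    gr[n + 4 * g] = g_b0 - beta0 / (beta_sd * beta_sd);
    gr[n + 4 * g + 1] = g_b1 - beta1 / (beta_sd * beta_sd);
  } else {
    gr[n + 4 * g] = 0.0;
    gr[n + 4 * g + 1] = 0.0;
  }
  return List::create(_["value"] = lp, _["gradient"] = gr);
}
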