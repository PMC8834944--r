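#include <Rcpp.h>
using namespace Rcpp;

// Adaptive single-site Metropolis-within-Gibbs sampler for the Poisson
// shared-component index model
//
//   y[i,k] ~ Poisson(theta[i,k] * E[i,k])
//   log theta[i,k] = alpha_k + beta_k * sum_j w_j q[i,j] + u_i + v_i + s[i,k]
//
// with w on the C-simplex (Dirichlet prior, sampled on the softmax scale
// with Jacobian correction), u_i iid Normal(0, 1/tau_u), v and each s_k
// intrinsic CAR, conjugate Gamma updates for all precisions, and a
// Uniform(0, sigma_beta_upper) prior on the sd of the Normal beta prior.
//
// q arrives column-centered; stored alpha draws are mapped back to the raw
// decile scale via alpha_k - beta_k * sum_j w_j qbar_j.  ICAR components are
// recentred each sweep with the mean transferred into the flat-prior
// intercepts, which leaves the posterior invariant.

namespace {

inline double cell_ll(double y, double E, double eta) {
  // log Poisson kernel up to additive constants in y
  return y * eta - E * std::exp(eta);
}

struct Adapt {
  std::vector<double> ls;   // log proposal sd
  std::vector<int> acc;
  Adapt(int n, double init) : ls(n, std::log(init)), acc(n, 0) {}
  void bump(int j) { acc[j]++; }
  void adapt(double target, int batch, double delta) {
    for (size_t j = 0; j < ls.size(); ++j) {
      double rate = (double)acc[j] / batch;
      ls[j] += (rate > target ? delta : -delta);
      if (ls[j] > 5.0) ls[j] = 5.0;
      if (ls[j] < -8.0) ls[j] = -8.0;
      acc[j] = 0;
    }
  }
};

} // namespace

// [[Rcpp::export]]
List ndi_mcmc_chain(const NumericMatrix y, const NumericMatrix E,
                    const NumericMatrix q, const NumericVector qbar,
                    const IntegerVector adj_idx, const IntegerVector adj_start,
                    const int n_components,
                    const NumericVector dir_alpha,
                    const double beta_prior_mean,
                    const double sigma_beta_upper,
                    const double tau_shape, const double tau_rate,
                    const bool include_u, const bool include_v,
                    const bool include_s, const bool prior_only,
                    const int n_iter, const int n_burnin, const int thin,
                    const NumericVector alpha0, const NumericVector beta0,
                    const NumericVector phi0, const double sigma_beta0,
                    const int adapt_batch, const double accept_target) {
  const int n = y.nrow(), K = y.ncol(), C = q.ncol();
  const int n_store = (n_iter - n_burnin + thin - 1) / thin;

  // state
  std::vector<double> alpha(alpha0.begin(), alpha0.end());
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> phi(phi0.begin(), phi0.end()); // phi[0] fixed at 0
  std::vector<double> w(C), ndi(n), u(n, 0.0), v(n, 0.0);
  std::vector<double> s(n * K, 0.0);
  double sigma_beta = sigma_beta0;
  double tau_u = 10.0, tau_v = 10.0;
  std::vector<double> tau_s(K, 10.0);

  auto softmax = [&](const std::vector<double>& p, std::vector<double>& out) {
    double mx = *std::max_element(p.begin(), p.end());
    double sum = 0.0;
    for (int j = 0; j < C; ++j) { out[j] = std::exp(p[j] - mx); sum += out[j]; }
    for (int j = 0; j < C; ++j) out[j] /= sum;
  };
  auto compute_ndi = [&](const std::vector<double>& ww, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int j = 0; j < C; ++j) acc += ww[j] * q(i, j);
      out[i] = acc;
    }
  };
  softmax(phi, w);
  compute_ndi(w, ndi);

  auto eta_cell = [&](int i, int k) {
    return alpha[k] + beta[k] * ndi[i] + u[i] + v[i] + s[i + n * k];
  };

  // proposal scales
  Adapt ad_alpha(K, 0.1), ad_beta(K, 0.1), ad_phi(C, 0.2), ad_sigma(1, 0.5);
  Adapt ad_u(n, 0.3), ad_v(n, 0.3), ad_s(n * K, 0.3);

  // storage
  NumericMatrix st_alpha(n_store, K), st_beta(n_store, K), st_w(n_store, C);
  NumericMatrix st_u(n_store, n), st_v(n_store, n), st_s(n_store, n * K);
  NumericVector st_tau_u(n_store), st_tau_v(n_store), st_sigma(n_store);
  NumericMatrix st_tau_s(n_store, K);

  const bool lik = !prior_only;
  int batch_num = 0;
  int stored = 0;

  std::vector<double> w_prop(C), ndi_prop(n);

  for (int iter = 0; iter < n_iter; ++iter) {
    const bool adapting = iter < n_burnin;

    if (lik) {
      // alpha_k: flat prior, column likelihood
      for (int k = 0; k < K; ++k) {
        double step = std::exp(ad_alpha.ls[k]);
        double prop = alpha[k] + norm_rand() * step;
        double d = 0.0;
        for (int i = 0; i < n; ++i) {
          double e0 = eta_cell(i, k);
          d += cell_ll(y(i, k), E(i, k), e0 + (prop - alpha[k])) -
               cell_ll(y(i, k), E(i, k), e0);
        }
        if (std::log(unif_rand()) < d) { alpha[k] = prop; ad_alpha.bump(k); }
      }
    }

    // beta_k: Normal(beta_prior_mean, sigma_beta^2) prior
    for (int k = 0; k < K; ++k) {
      double step = std::exp(ad_beta.ls[k]);
      double prop = beta[k] + norm_rand() * step;
      double d = R::dnorm(prop, beta_prior_mean, sigma_beta, 1) -
                 R::dnorm(beta[k], beta_prior_mean, sigma_beta, 1);
      if (lik) {
        for (int i = 0; i < n; ++i) {
          double e0 = eta_cell(i, k);
          d += cell_ll(y(i, k), E(i, k), e0 + (prop - beta[k]) * ndi[i]) -
               cell_ll(y(i, k), E(i, k), e0);
        }
      }
      if (std::log(unif_rand()) < d) { beta[k] = prop; ad_beta.bump(k); }
    }

    // sigma_beta: Uniform(0, upper) prior on the sd
    {
      double step = std::exp(ad_sigma.ls[0]);
      double prop = sigma_beta + norm_rand() * step;
      if (prop > 0.0 && prop < sigma_beta_upper) {
        double d = 0.0;
        for (int k = 0; k < K; ++k)
          d += R::dnorm(beta[k], beta_prior_mean, prop, 1) -
               R::dnorm(beta[k], beta_prior_mean, sigma_beta, 1);
        if (std::log(unif_rand()) < d) { sigma_beta = prop; ad_sigma.bump(0); }
      }
    }

    // weights via softmax coordinates phi[1..C-1] (phi[0] pinned at 0);
    // target = Dirichlet(dir_alpha) x Jacobian prod(w_j) = prod w_j^dir_alpha
    for (int j = 1; j < C; ++j) {
      double step = std::exp(ad_phi.ls[j]);
      std::vector<double> phi_prop(phi);
      phi_prop[j] += norm_rand() * step;
      softmax(phi_prop, w_prop);
      double d = 0.0;
      for (int c = 0; c < C; ++c)
        d += dir_alpha[c] * (std::log(w_prop[c]) - std::log(w[c]));
      if (lik) {
        compute_ndi(w_prop, ndi_prop);
        for (int k = 0; k < K; ++k) {
          if (beta[k] == 0.0) continue;
          for (int i = 0; i < n; ++i) {
            double e0 = eta_cell(i, k);
            d += cell_ll(y(i, k), E(i, k), e0 + beta[k] * (ndi_prop[i] - ndi[i])) -
                 cell_ll(y(i, k), E(i, k), e0);
          }
        }
      }
      if (std::log(unif_rand()) < d) {
        phi = phi_prop;
        w = w_prop;
        if (lik) ndi = ndi_prop; else compute_ndi(w, ndi);
        ad_phi.bump(j);
      }
    }

    if (lik && include_u) {
      // u_i iid Normal(0, 1/tau_u)
      for (int i = 0; i < n; ++i) {
        double step = std::exp(ad_u.ls[i]);
        double prop = u[i] + norm_rand() * step;
        double d = -0.5 * tau_u * (prop * prop - u[i] * u[i]);
        for (int k = 0; k < K; ++k) {
          double e0 = eta_cell(i, k);
          d += cell_ll(y(i, k), E(i, k), e0 + (prop - u[i])) -
               cell_ll(y(i, k), E(i, k), e0);
        }
        if (std::log(unif_rand()) < d) { u[i] = prop; ad_u.bump(i); }
      }
      double ssq = 0.0;
      for (int i = 0; i < n; ++i) ssq += u[i] * u[i];
      tau_u = R::rgamma(tau_shape + 0.5 * n, 1.0 / (tau_rate + 0.5 * ssq));
    }

    if (lik && include_v) {
      // v: ICAR(tau_v), full conditional Normal(mean of neighbours, 1/(tau m_i))
      for (int i = 0; i < n; ++i) {
        int m = adj_start[i + 1] - adj_start[i];
        if (m == 0) continue;
        double nbr_mean = 0.0;
        for (int a = adj_start[i]; a < adj_start[i + 1]; ++a)
          nbr_mean += v[adj_idx[a]];
        nbr_mean /= m;
        double step = std::exp(ad_v.ls[i]);
        double prop = v[i] + norm_rand() * step;
        double d = -0.5 * tau_v * m *
                   ((prop - nbr_mean) * (prop - nbr_mean) -
                    (v[i] - nbr_mean) * (v[i] - nbr_mean));
        for (int k = 0; k < K; ++k) {
          double e0 = eta_cell(i, k);
          d += cell_ll(y(i, k), E(i, k), e0 + (prop - v[i])) -
               cell_ll(y(i, k), E(i, k), e0);
        }
        if (std::log(unif_rand()) < d) { v[i] = prop; ad_v.bump(i); }
      }
      // recentre; transfer the mean into the flat-prior intercepts
      double vm = 0.0;
      for (int i = 0; i < n; ++i) vm += v[i];
      vm /= n;
      for (int i = 0; i < n; ++i) v[i] -= vm;
      for (int k = 0; k < K; ++k) alpha[k] += vm;
      // conjugate precision update
      double Q = 0.0;
      for (int i = 0; i < n; ++i)
        for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
          int j = adj_idx[a];
          if (j > i) { double dv = v[i] - v[j]; Q += dv * dv; }
        }
      tau_v = R::rgamma(tau_shape + 0.5 * (n - n_components),
                        1.0 / (tau_rate + 0.5 * Q));
    }

    if (lik && include_s) {
      for (int k = 0; k < K; ++k) {
        double* sk = &s[n * k];
        for (int i = 0; i < n; ++i) {
          int m = adj_start[i + 1] - adj_start[i];
          if (m == 0) continue;
          double nbr_mean = 0.0;
          for (int a = adj_start[i]; a < adj_start[i + 1]; ++a)
            nbr_mean += sk[adj_idx[a]];
          nbr_mean /= m;
          int idx = i + n * k;
          double step = std::exp(ad_s.ls[idx]);
          double prop = sk[i] + norm_rand() * step;
          double d = -0.5 * tau_s[k] * m *
                     ((prop - nbr_mean) * (prop - nbr_mean) -
                      (sk[i] - nbr_mean) * (sk[i] - nbr_mean));
          double e0 = eta_cell(i, k);
          d += cell_ll(y(i, k), E(i, k), e0 + (prop - sk[i])) -
               cell_ll(y(i, k), E(i, k), e0);
          if (std::log(unif_rand()) < d) { sk[i] = prop; ad_s.bump(idx); }
        }
        double sm = 0.0;
        for (int i = 0; i < n; ++i) sm += sk[i];
        sm /= n;
        for (int i = 0; i < n; ++i) sk[i] -= sm;
        alpha[k] += sm;
        double Q = 0.0;
        for (int i = 0; i < n; ++i)
          for (int a = adj_start[i]; a < adj_start[i + 1]; ++a) {
            int j = adj_idx[a];
            if (j > i) { double ds = sk[i] - sk[j]; Q += ds * ds; }
          }
        tau_s[k] = R::rgamma(tau_shape + 0.5 * (n - n_components),
                             1.0 / (tau_rate + 0.5 * Q));
      }
    }

    // proposal adaptation: burn-in only, frozen afterwards
    if (adapting && (iter + 1) % adapt_batch == 0) {
      batch_num++;
      double delta = std::min(0.05, 1.0 / std::sqrt((double)batch_num));
      ad_alpha.adapt(accept_target, adapt_batch, delta);
      ad_beta.adapt(accept_target, adapt_batch, delta);
      ad_phi.adapt(accept_target, adapt_batch, delta);
      ad_sigma.adapt(accept_target, adapt_batch, delta);
      ad_u.adapt(accept_target, adapt_batch, delta);
      ad_v.adapt(accept_target, adapt_batch, delta);
      ad_s.adapt(accept_target, adapt_batch, delta);
    }

    if (iter >= n_burnin && (iter - n_burnin) % thin == 0 && stored < n_store) {
      double wq = 0.0;
      for (int j = 0; j < C; ++j) wq += w[j] * qbar[j];
      for (int k = 0; k < K; ++k) {
        st_alpha(stored, k) = alpha[k] - beta[k] * wq; // raw decile scale
        st_beta(stored, k) = beta[k];
        st_tau_s(stored, k) = tau_s[k];
      }
      for (int j = 0; j < C; ++j) st_w(stored, j) = w[j];
      for (int i = 0; i < n; ++i) {
        st_u(stored, i) = u[i];
        st_v(stored, i) = v[i];
      }
      for (int idx = 0; idx < n * K; ++idx) st_s(stored, idx) = s[idx];
      st_tau_u[stored] = tau_u;
      st_tau_v[stored] = tau_v;
      st_sigma[stored] = sigma_beta;
      stored++;
    }

    if ((iter + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["alpha"] = st_alpha, _["beta"] = st_beta, _["w"] = st_w,
      _["u"] = st_u, _["v"] = st_v, _["s"] = st_s,
      _["tau_u"] = st_tau_u, _["tau_v"] = st_tau_v, _["tau_s"] = st_tau_s,
      _["sigma_beta"] = st_sigma);
}

// Optimal string alignment (restricted Damerau-Levenshtein) distance.
// Unit-cost insertions, deletions, substitutions and adjacent
// transpositions; no substring is edited more than once.
// [[Rcpp::export]]
int osa_distance_cpp(const std::string& a, const std::string& b) {
  const int la = a.size(), lb = b.size();
  if (la == 0) return lb;
  if (lb == 0) return la;
  std::vector<std::vector<int> > d(la + 1, std::vector<int>(lb + 1, 0));
  for (int i = 0; i <= la; ++i) d[i][0] = i;
  for (int j = 0; j <= lb; ++j) d[0][j] = j;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int cost = (a[i - 1] == b[j - 1]) ? 0 : 1;
      int best = std::min(std::min(d[i - 1][j] + 1, d[i][j - 1] + 1),
                          d[i - 1][j - 1] + cost);
      if (i > 1 && j > 1 && a[i - 1] == b[j - 2] && a[i - 2] == b[j - 1])
        best = std::min(best, d[i - 2][j - 2] + 1);
      d[i][j] = best;
    }
  }
  return d[la][lb];
}
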