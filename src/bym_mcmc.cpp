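#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// One MCMC chain for the Poisson BYM model
//   y_i ~ Poisson(exp(eta_i)),  eta_i = alpha + X_i beta + logpop_i + u_i + st_i
//   u_i ~ N(0, 1/tau_u),  st ~ ICAR(tau_st) with sum-to-zero,
//   tau_u ~ Gamma(a_u, b_u), tau_st ~ Gamma(a_st, b_st)  (logGamma on log tau),
//   alpha, beta_j ~ N(0, prior_var[j]).
//
// Updates: single-site adaptive random-walk Metropolis for alpha, beta, u, st;
// conjugate Gibbs for the two precisions; st recentred each sweep with the
// mean transferred into alpha. Uses R's RNG, so set.seed() upstream gives
// full reproducibility. X is expected standardised by the caller for mixing.

static inline double rnorm1(double sd) { return R::rnorm(0.0, sd); }

// [[Rcpp::export]]
List bym_chain_cpp(const IntegerVector& y, const NumericVector& logpop,
                   const NumericMatrix& X, const List& nb,
                   const NumericVector& prior_var,
                   double a_u, double b_u, double a_st, double b_st,
                   bool use_u, bool use_st,
                   int burnin, int n_keep, int thin) {
  RNGScope scope;
  const int n = y.size();
  const int p = X.ncol();

  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector v = nb[i];
    adj[i].reserve(v.size());
    for (int k = 0; k < v.size(); ++k) adj[i].push_back(v[k] - 1);
  }

  double sumy = 0.0, sumpop = 0.0;
  std::vector<double> sxy(p, 0.0);
  for (int i = 0; i < n; ++i) {
    sumy += y[i];
    sumpop += std::exp(logpop[i]);
    for (int j = 0; j < p; ++j) sxy[j] += y[i] * X(i, j);
  }

  // state
  double alpha = std::log((sumy + 0.5) / sumpop);
  std::vector<double> beta(p, 0.0), u(n, 0.0), st(n, 0.0);
  double tau_u = 10.0, tau_st = 10.0;
  std::vector<double> eta(n), lambda(n);
  double sumlambda = 0.0;
  for (int i = 0; i < n; ++i) {
    eta[i] = alpha + logpop[i];
    lambda[i] = std::exp(eta[i]);
    sumlambda += lambda[i];
  }

  // adaptive proposal scales
  double s_alpha = 0.05, s_u = 0.5, s_st = 0.5;
  double s_ridge_a = 0.1;
  std::vector<double> s_beta(p, 0.05), s_ridge_b(p, 0.1);
  int acc_alpha = 0, att_alpha = 0, acc_u = 0, att_u = 0, acc_st = 0, att_st = 0;
  int acc_ra = 0, att_ra = 0, acc_sw = 0, att_sw = 0;
  double s_swap = 0.1;
  std::vector<double> s_ridge_s(p, 0.1);
  std::vector<int> acc_beta(p, 0), att_beta(p, 0), acc_rb(p, 0), att_rb(p, 0),
                   acc_rs(p, 0), att_rs(p, 0);
  std::vector< std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (size_t k = 0; k < adj[i].size(); ++k)
      if (adj[i][k] > i) edges.push_back(std::make_pair(i, adj[i][k]));
  const double lo = 0.35, hi = 0.50;  // single-site acceptance window

  const int n_iter = burnin + n_keep * thin;
  NumericVector alpha_out(n_keep), tau_u_out(n_keep), tau_st_out(n_keep),
                dev_out(n_keep);
  NumericMatrix beta_out(n_keep, p), u_out(n_keep, n), st_out(n_keep, n);
  NumericVector eta_hat(n);  // running sum of kept eta draws
  int kept = 0;

  double lgam = 0.0;  // sum of lgamma(y_i + 1), constant in the deviance
  for (int i = 0; i < n; ++i) lgam += R::lgammafn((double)y[i] + 1.0);

  for (int it = 0; it < n_iter; ++it) {
    // --- alpha: O(1) via sufficient statistics ---
    {
      double d = rnorm1(s_alpha);
      double an = alpha + d;
      double dll = d * sumy - (std::exp(d) - 1.0) * sumlambda
                   - (an * an - alpha * alpha) / (2.0 * prior_var[0]);
      ++att_alpha;
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        alpha = an;
        double f = std::exp(d);
        for (int i = 0; i < n; ++i) { eta[i] += d; lambda[i] *= f; }
        sumlambda *= f;
        ++acc_alpha;
      }
    }
    // --- beta: single-site, O(n) each ---
    for (int j = 0; j < p; ++j) {
      double d = rnorm1(s_beta[j]);
      double bn = beta[j] + d;
      double dll = d * sxy[j]
                   - (bn * bn - beta[j] * beta[j]) / (2.0 * prior_var[j + 1]);
      double dlam = 0.0;
      for (int i = 0; i < n; ++i) dlam += lambda[i] * (std::exp(d * X(i, j)) - 1.0);
      dll -= dlam;
      ++att_beta[j];
      if (std::log(R::runif(0.0, 1.0)) < dll) {
        beta[j] = bn;
        sumlambda = 0.0;
        for (int i = 0; i < n; ++i) {
          eta[i] += d * X(i, j);
          lambda[i] = std::exp(eta[i]);
          sumlambda += lambda[i];
        }
        ++acc_beta[j];
      }
    }
    // --- u: single-site, O(1) each ---
    if (use_u) {
      for (int i = 0; i < n; ++i) {
        double d = rnorm1(s_u);
        double un = u[i] + d;
        double dll = y[i] * d - lambda[i] * (std::exp(d) - 1.0)
                     - 0.5 * tau_u * (un * un - u[i] * u[i]);
        ++att_u;
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          u[i] = un;
          eta[i] += d;
          double nl = std::exp(eta[i]);
          sumlambda += nl - lambda[i];
          lambda[i] = nl;
          ++acc_u;
        }
      }
      double ssu = 0.0;
      for (int i = 0; i < n; ++i) ssu += u[i] * u[i];
      tau_u = R::rgamma(a_u + 0.5 * n, 1.0 / (b_u + 0.5 * ssu));
    }
    // --- st: single-site with ICAR full-conditional prior ---
    if (use_st) {
      for (int i = 0; i < n; ++i) {
        int deg = adj[i].size();
        if (deg == 0) continue;  // islands carry no structured effect update
        double m = 0.0;
        for (int k = 0; k < deg; ++k) m += st[adj[i][k]];
        m /= deg;
        double d = rnorm1(s_st);
        double sn = st[i] + d;
        double dll = y[i] * d - lambda[i] * (std::exp(d) - 1.0)
                     - 0.5 * tau_st * deg * ((sn - m) * (sn - m) - (st[i] - m) * (st[i] - m));
        ++att_st;
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          st[i] = sn;
          eta[i] += d;
          double nl = std::exp(eta[i]);
          sumlambda += nl - lambda[i];
          lambda[i] = nl;
          ++acc_st;
        }
      }
      // hard sum-to-zero: transfer the mean into the intercept
      double m = 0.0;
      for (int i = 0; i < n; ++i) m += st[i];
      m /= n;
      for (int i = 0; i < n; ++i) st[i] -= m;
      alpha += m;
      double pairsum = 0.0;
      for (int i = 0; i < n; ++i)
        for (size_t k = 0; k < adj[i].size(); ++k) {
          int j2 = adj[i][k];
          if (j2 > i) { double dd = st[i] - st[j2]; pairsum += dd * dd; }
        }
      tau_st = R::rgamma(a_st + 0.5 * (n - 1.0), 1.0 / (b_st + 0.5 * pairsum));
    }

    // --- ridge (interweaving) moves: shift a fixed effect and compensate
    // u so the likelihood is untouched; only prior terms enter the ratio.
    // These travel along the beta/random-effect ridge that single-site
    // updates cross slowly.
    if (use_u) {
      {
        double d = rnorm1(s_ridge_a);
        double an = alpha + d;
        double sumu = 0.0;
        for (int i = 0; i < n; ++i) sumu += u[i];
        double dll = -0.5 * tau_u * (-2.0 * d * sumu + n * d * d)
                     - (an * an - alpha * alpha) / (2.0 * prior_var[0]);
        ++att_ra;
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          alpha = an;
          for (int i = 0; i < n; ++i) u[i] -= d;
          ++acc_ra;
        }
      }
      for (int j = 0; j < p; ++j) {
        double d = rnorm1(s_ridge_b[j]);
        double bn = beta[j] + d;
        double dpen = 0.0;
        for (int i = 0; i < n; ++i) {
          double un = u[i] - d * X(i, j);
          dpen += un * un - u[i] * u[i];
        }
        double dll = -0.5 * tau_u * dpen
                     - (bn * bn - beta[j] * beta[j]) / (2.0 * prior_var[j + 1]);
        ++att_rb[j];
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          beta[j] = bn;
          for (int i = 0; i < n; ++i) u[i] -= d * X(i, j);
          ++acc_rb[j];
        }
      }
    }

    // u/st swap: u' = u + d*st, st' = (1-d)*st leaves u + st (hence the
    // likelihood) unchanged and trades variance between the two fields,
    // the weakly identified direction of the convolution model. The ICAR
    // field lives on an (n-1)-dim subspace, so the Jacobian is (1-d)^(n-1).
    if (use_u && use_st) {
      double d = rnorm1(s_swap);
      if (std::fabs(1.0 - d) > 1e-12) {
        double ssu_old = 0.0, ssu_new = 0.0, pairsum = 0.0;
        for (int i = 0; i < n; ++i) {
          double un = u[i] + d * st[i];
          ssu_old += u[i] * u[i];
          ssu_new += un * un;
        }
        for (size_t e = 0; e < edges.size(); ++e) {
          double diff = st[edges[e].first] - st[edges[e].second];
          pairsum += diff * diff;
        }
        double dll = -0.5 * tau_u * (ssu_new - ssu_old)
                     - 0.5 * tau_st * ((1.0 - d) * (1.0 - d) - 1.0) * pairsum
                     + (n - 1.0) * std::log(std::fabs(1.0 - d));
        ++att_sw;
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          for (int i = 0; i < n; ++i) {
            u[i] += d * st[i];
            st[i] *= (1.0 - d);
          }
          ++acc_sw;
        }
      }
    }

    // beta/st ridge: shift beta_j, compensate st by -d * x_j (x_j is
    // centred, so the sum-to-zero constraint is preserved); only the ICAR
    // pairwise penalty and the beta prior change.
    if (use_st) {
      for (int j = 0; j < p; ++j) {
        double d = rnorm1(s_ridge_s[j]);
        double bn = beta[j] + d;
        double dpen = 0.0;
        for (size_t e = 0; e < edges.size(); ++e) {
          int i1 = edges[e].first, i2 = edges[e].second;
          double diff = st[i1] - st[i2];
          double nd = diff - d * (X(i1, j) - X(i2, j));
          dpen += nd * nd - diff * diff;
        }
        double dll = -0.5 * tau_st * dpen
                     - (bn * bn - beta[j] * beta[j]) / (2.0 * prior_var[j + 1]);
        ++att_rs[j];
        if (std::log(R::runif(0.0, 1.0)) < dll) {
          beta[j] = bn;
          for (int i = 0; i < n; ++i) st[i] -= d * X(i, j);
          ++acc_rs[j];
        }
      }
    }

    // --- adapt proposal scales during burn-in ---
    if (it < burnin && (it + 1) % 100 == 0) {
      if (att_alpha) {
        double r = (double)acc_alpha / att_alpha;
        if (r > hi) s_alpha *= 1.3; else if (r < lo) s_alpha /= 1.3;
      }
      for (int j = 0; j < p; ++j) if (att_beta[j]) {
        double r = (double)acc_beta[j] / att_beta[j];
        if (r > hi) s_beta[j] *= 1.3; else if (r < lo) s_beta[j] /= 1.3;
      }
      if (att_u) {
        double r = (double)acc_u / att_u;
        if (r > hi) s_u *= 1.3; else if (r < lo) s_u /= 1.3;
      }
      if (att_st) {
        double r = (double)acc_st / att_st;
        if (r > hi) s_st *= 1.3; else if (r < lo) s_st /= 1.3;
      }
      if (att_ra) {
        double r = (double)acc_ra / att_ra;
        if (r > hi) s_ridge_a *= 1.3; else if (r < lo) s_ridge_a /= 1.3;
      }
      if (att_sw) {
        double r = (double)acc_sw / att_sw;
        if (r > hi) s_swap *= 1.3; else if (r < lo) s_swap /= 1.3;
      }
      acc_sw = att_sw = 0;
      for (int j = 0; j < p; ++j) if (att_rb[j]) {
        double r = (double)acc_rb[j] / att_rb[j];
        if (r > hi) s_ridge_b[j] *= 1.3; else if (r < lo) s_ridge_b[j] /= 1.3;
      }
      for (int j = 0; j < p; ++j) if (att_rs[j]) {
        double r = (double)acc_rs[j] / att_rs[j];
        if (r > hi) s_ridge_s[j] *= 1.3; else if (r < lo) s_ridge_s[j] /= 1.3;
      }
      acc_alpha = att_alpha = acc_u = att_u = acc_st = att_st = 0;
      acc_ra = att_ra = 0;
      std::fill(acc_beta.begin(), acc_beta.end(), 0);
      std::fill(att_beta.begin(), att_beta.end(), 0);
      std::fill(acc_rb.begin(), acc_rb.end(), 0);
      std::fill(att_rb.begin(), att_rb.end(), 0);
      std::fill(acc_rs.begin(), acc_rs.end(), 0);
      std::fill(att_rs.begin(), att_rs.end(), 0);
    }

    // --- store ---
    if (it >= burnin && (it - burnin + 1) % thin == 0) {
      alpha_out[kept] = alpha;
      for (int j = 0; j < p; ++j) beta_out(kept, j) = beta[j];
      for (int i = 0; i < n; ++i) { u_out(kept, i) = u[i]; st_out(kept, i) = st[i]; }
      tau_u_out[kept] = use_u ? tau_u : NA_REAL;
      tau_st_out[kept] = use_st ? tau_st : NA_REAL;
      double ll = -lgam;
      for (int i = 0; i < n; ++i) {
        ll += y[i] * eta[i] - lambda[i];
        eta_hat[i] += eta[i];
      }
      dev_out[kept] = -2.0 * ll;
      ++kept;
    }
  }
  for (int i = 0; i < n; ++i) eta_hat[i] /= n_keep;

  return List::create(
    _["alpha"] = alpha_out, _["beta"] = beta_out,
    _["u"] = u_out, _["st"] = st_out,
    _["tau_u"] = tau_u_out, _["tau_st"] = tau_st_out,
    _["deviance"] = dev_out, _["eta_hat"] = eta_hat
  );
}
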