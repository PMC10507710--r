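#include <Rcpp.h>
using namespace Rcpp;

// Inverse-Gaussian draw (Michael, Schucany & Haas 1976), uses R's RNG so
// set.seed() in the calling R session governs reproducibility.
static double rinvgauss(double mu, double lambda) {
  double z = norm_rand();
  double y = z * z;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0.0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

// Gibbs sampler for the Bayesian LASSO (Park & Casella 2008 scale-mixture
// representation): y = X beta + M f + e, flat prior on beta, double
// exponential prior on f via f_j ~ N(0, sigma2 tau2_j), tau2_j ~ Exp(l2/2),
// l2 ~ Gamma(lshape, lrate), sigma2 ~ scaled-inv-chi2(df0, S0).
// [[Rcpp::export]]
List bl_gibbs_cpp(NumericVector y, NumericMatrix X, NumericMatrix M,
                  int n_iter, int burn_in, int thin,
                  double df0, double S0, double lshape, double lrate,
                  double lambda2_init) {
  int n = y.size(), px = X.ncol(), p = M.ncol();
  NumericVector beta(px), f(p), invtau2(p, 1.0);
  double sigma2 = 1.0, lambda2 = lambda2_init;

  // column cross-products
  NumericVector cx(px), cm(p);
  for (int j = 0; j < px; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    cx[j] = s;
  }
  for (int j = 0; j < p; ++j) {
    double s = 0; for (int i = 0; i < n; ++i) s += M(i, j) * M(i, j);
    if (s <= 0) s = 1e-12;
    cm[j] = s;
  }

  // residual e = y - X beta - M f (beta, f start at 0)
  NumericVector e = clone(y);
  // crude variance init
  double ybar = mean(y);
  double vy = 0; for (int i = 0; i < n; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy /= std::max(n - 1, 1);
  sigma2 = 0.5 * vy + 1e-8;

  NumericVector beta_s(px), f_s(p), g_s(n);
  double s2_s = 0, l2_s = 0;
  int n_kept = 0;

  GetRNGstate();
  for (int it = 1; it <= n_iter; ++it) {
    // fixed effects, flat prior, coordinate-wise
    for (int j = 0; j < px; ++j) {
      double old = beta[j];
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += X(i, j) * (e[i] + X(i, j) * old);
      double mu = rhs / cx[j];
      double nv = mu + norm_rand() * std::sqrt(sigma2 / cx[j]);
      double d = nv - old;
      for (int i = 0; i < n; ++i) e[i] -= X(i, j) * d;
      beta[j] = nv;
    }
    // marker/haplotype effects
    for (int j = 0; j < p; ++j) {
      double old = f[j];
      double rhs = 0;
      for (int i = 0; i < n; ++i) rhs += M(i, j) * e[i];
      rhs += cm[j] * old;
      double prec = cm[j] + invtau2[j];
      double mu = rhs / prec;
      double nv = mu + norm_rand() * std::sqrt(sigma2 / prec);
      double d = nv - old;
      for (int i = 0; i < n; ++i) e[i] -= M(i, j) * d;
      f[j] = nv;
    }
    // latent scales
    double sum_tau2 = 0;
    for (int j = 0; j < p; ++j) {
      double fj2 = f[j] * f[j];
      if (fj2 < 1e-20) fj2 = 1e-20;
      double mu = std::sqrt(lambda2 * sigma2 / fj2);
      if (mu > 1e8) mu = 1e8;
      invtau2[j] = rinvgauss(mu, lambda2);
      sum_tau2 += 1.0 / invtau2[j];
    }
    // shrinkage hyperparameter
    lambda2 = R::rgamma(p + lshape, 1.0 / (sum_tau2 / 2.0 + lrate));
    // residual variance (f | sigma2 scaled jointly)
    double sse = 0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    double ssf = 0;
    for (int j = 0; j < p; ++j) ssf += f[j] * f[j] * invtau2[j];
    sigma2 = (sse + ssf + S0) / R::rchisq((double)(n + p) + df0);
    if (!R_finite(sigma2) || !R_finite(lambda2)) {
      PutRNGstate();
      stop("Bayesian LASSO chain diverged at iteration %d", it);
    }

    if (it > burn_in && ((it - burn_in) % thin == 0)) {
      ++n_kept;
      for (int j = 0; j < px; ++j) beta_s[j] += beta[j];
      for (int j = 0; j < p; ++j) f_s[j] += f[j];
      for (int i = 0; i < n; ++i) {
        double xb = 0;
        for (int j = 0; j < px; ++j) xb += X(i, j) * beta[j];
        g_s[i] += y[i] - e[i] - xb;      // = (M f)_i
      }
      s2_s += sigma2;
      l2_s += lambda2;
    }
  }
  PutRNGstate();

  if (n_kept == 0) stop("no samples kept: check n_iter/burn_in/thin");
  for (int j = 0; j < px; ++j) beta_s[j] /= n_kept;
  for (int j = 0; j < p; ++j) f_s[j] /= n_kept;
  for (int i = 0; i < n; ++i) g_s[i] /= n_kept;
  return List::create(_["beta"] = beta_s, _["effects"] = f_s,
                      _["genetic_values"] = g_s,
                      _["sigma2_e"] = s2_s / n_kept,
                      _["lambda2"] = l2_s / n_kept,
                      _["n_kept"] = n_kept);
}
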