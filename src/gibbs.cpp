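#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gibbs sampler for the full QTS hierarchical linear model.
//
// y = X beta + eps,  eps ~ N(0, sigma2 I)
// Column j of X carries coefficient beta_j with prior
//   group[j] == 0 : fixed effect (mu, a, aa), beta_j ~ N(0, tau2_fixed)
//   group[j] == g : random effect in family g (1 = environment, 2 = ae,
//                   3 = aae), beta_j ~ N(0, sigma2_g), one variance
//                   component per family.
// Family variances and sigma2 have inverse-gamma(a0, b0) priors.
// Scalar (single-site) conjugate updates with a running residual; uses
// R's RNG so results are reproducible under set.seed().
//
// Returns kept draws of beta (rows = draws) and of the variance
// components (environment, ae, aae where present, and residual).

// [[Rcpp::export(name = ".gibbs_qts")]]
List gibbs_qts(NumericMatrix X, NumericVector y, IntegerVector group,
               double tau2_fixed, double a0, double b0,
               int iterations, int burnin, int thin) {
  const int N = X.nrow(), P = X.ncol();
  if (y.size() != N) stop("dimension mismatch");
  if (burnin >= iterations) stop("burnin must be below iterations");
  if (thin < 1) stop("thin must be >= 1");

  int ngroup = 0;
  for (int j = 0; j < P; ++j) ngroup = std::max(ngroup, group[j]);

  std::vector<double> xtx(P);
  for (int j = 0; j < P; ++j) {
    double s = 0;
    for (int i = 0; i < N; ++i) s += X(i, j) * X(i, j);
    xtx[j] = s;
  }

  double ybar = mean(y);
  double vy = 0;
  for (int i = 0; i < N; ++i) vy += (y[i] - ybar) * (y[i] - ybar);
  vy = vy / std::max(1, N - 1);
  if (vy <= 0) vy = 1.0;

  std::vector<double> beta(P, 0.0), r(y.begin(), y.end());
  double sigma2 = vy / 2.0;
  std::vector<double> sigma2_g(ngroup + 1, vy / 4.0);
  std::vector<int> gsize(ngroup + 1, 0);
  for (int j = 0; j < P; ++j) if (group[j] > 0) ++gsize[group[j]];

  const int nkeep = (iterations - burnin + thin - 1) / thin;
  NumericMatrix beta_draws(nkeep, P);
  NumericMatrix var_draws(nkeep, ngroup + 1); // families 1..ngroup, then residual

  RNGScope scope;
  int kept = 0;
  for (int it = 0; it < iterations; ++it) {
    for (int j = 0; j < P; ++j) {
      double prior_v = (group[j] == 0) ? tau2_fixed : sigma2_g[group[j]];
      if (xtx[j] <= 0 && prior_v <= 0) continue;
      double prec = xtx[j] / sigma2 + 1.0 / prior_v;
      double s2 = 1.0 / prec;
      double xr = 0;
      const double* xj = &X(0, j);
      for (int i = 0; i < N; ++i) xr += xj[i] * r[i];
      xr += xtx[j] * beta[j];
      double m = s2 * xr / sigma2;
      double nb = R::rnorm(m, std::sqrt(s2));
      double d = nb - beta[j];
      if (d != 0) {
        for (int i = 0; i < N; ++i) r[i] -= xj[i] * d;
        beta[j] = nb;
      }
    }
    for (int g = 1; g <= ngroup; ++g) {
      if (!gsize[g]) continue;
      double ss = 0;
      for (int j = 0; j < P; ++j) if (group[j] == g) ss += beta[j] * beta[j];
      double shape = a0 + gsize[g] / 2.0;
      double rate = b0 + ss / 2.0;
      sigma2_g[g] = 1.0 / R::rgamma(shape, 1.0 / rate);
    }
    double rss = 0;
    for (int i = 0; i < N; ++i) rss += r[i] * r[i];
    sigma2 = 1.0 / R::rgamma(a0 + N / 2.0, 1.0 / (b0 + rss / 2.0));

    if (it >= burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < P; ++j) beta_draws(kept, j) = beta[j];
      for (int g = 1; g <= ngroup; ++g) var_draws(kept, g - 1) = sigma2_g[g];
      var_draws(kept, ngroup) = sigma2;
      ++kept;
    }
  }
  return List::create(_["beta"] = beta_draws, _["variances"] = var_draws,
                      _["n_groups"] = ngroup);
}
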