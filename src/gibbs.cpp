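#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for the two-group normal model y_ij = mu_i + e_ij,
// e ~ N(0, sigma2), flat priors on the group means and the reference
// (Jeffreys) prior p(sigma2) proportional to 1/sigma2, so that the pooled
// posterior of D = mu_H - mu_L is the classical two-sample flat-prior t
// posterior with n - 2 degrees of freedom.
//
// Full conditionals:
//   mu_i | sigma2 ~ N(ybar_i, sigma2 / n_i)
//   sigma2 | mu   ~ Inv-Gamma(n/2, SSE(mu)/2),
//     SSE(mu) = SS_within + n_H (mu_H - ybar_H)^2 + n_L (mu_L - ybar_L)^2
//
// Uses R's RNG stream (determinism via set.seed on the R side).

// [[Rcpp::export]]
NumericVector gibbs_two_group_chain(double ybar_h, double ybar_l,
                                    double ss_within,
                                    int n_h, int n_l,
                                    int n_iter, int burn_in, int thin) {
  const int n = n_h + n_l;
  const int n_keep = (n_iter - burn_in) / thin;
  NumericVector draws(n_keep);
  double sigma2 = ss_within / (n - 2);
  if (!(sigma2 > 0)) sigma2 = 1e-12;  // degenerate data: floor the variance
  int k = 0;
  for (int it = 1; it <= n_iter; ++it) {
    const double mu_h = R::rnorm(ybar_h, std::sqrt(sigma2 / n_h));
    const double mu_l = R::rnorm(ybar_l, std::sqrt(sigma2 / n_l));
    double sse = ss_within
      + n_h * (mu_h - ybar_h) * (mu_h - ybar_h)
      + n_l * (mu_l - ybar_l) * (mu_l - ybar_l);
    if (!(sse > 0)) sse = 1e-12;
    sigma2 = 1.0 / R::rgamma(n / 2.0, 2.0 / sse);
    if (it > burn_in && (it - burn_in) % thin == 0 && k < n_keep)
      draws[k++] = mu_h - mu_l;
  }
  return draws;
}
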