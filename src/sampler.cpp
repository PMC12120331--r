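#include <Rcpp.h>
using namespace Rcpp;

// Identity-link Poisson log-likelihood for one parameter state.
// theta layout: [alpha, beta_1..beta_k, (beta_plus, beta_minus, thresh)].
// X holds the (centered) linear covariates, xm the (centered) modulated
// covariate, gov the *uncentered* governing covariate compared to the
// threshold. Returns -Inf when any mu <= 0 (positivity by rejection).
static double log_lik(const std::vector<double>& theta, const NumericVector& y,
                      const NumericMatrix& X, const NumericVector& xm,
                      const NumericVector& gov, bool has_thresh) {
  const int n = y.size(), k = X.ncol();
  double bp = 0.0, bm = 0.0, th = 0.0;
  if (has_thresh) {
    bp = theta[1 + k];
    bm = theta[2 + k];
    th = theta[3 + k];
  }
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double mu = theta[0];
    for (int j = 0; j < k; ++j) mu += theta[1 + j] * X(i, j);
    if (has_thresh) mu += (gov[i] > th ? bp : bm) * xm[i];
    if (mu <= 0.0) return R_NegInf;
    ll += R::dpois(y[i], mu, 1);
  }
  return ll;
}

static double log_post(const std::vector<double>& theta, const NumericVector& y,
                       const NumericMatrix& X, const NumericVector& xm,
                       const NumericVector& gov, bool has_thresh,
                       double tlo, double thi, double prior_sd) {
  const int k = X.ncol();
  if (has_thresh) {
    double th = theta[3 + k];
    if (th < tlo || th > thi) return R_NegInf;  // uniform threshold prior
  }
  double lp = R::dnorm(theta[0], 0.0, prior_sd, 1);
  for (int j = 0; j < k; ++j) lp += R::dnorm(theta[1 + j], 0.0, prior_sd, 1);
  if (has_thresh) {
    lp += R::dnorm(theta[1 + k], 0.0, prior_sd, 1);
    lp += R::dnorm(theta[2 + k], 0.0, prior_sd, 1);
  }
  double ll = log_lik(theta, y, X, xm, gov, has_thresh);
  if (!R_FINITE(ll)) return R_NegInf;
  return lp + ll;
}

// Componentwise Gaussian random-walk Metropolis with Robbins-Monro step
// adaptation (target acceptance `target_acc`) during burn-in only; step
// sizes are frozen before any draw is retained. Uses R's RNG so set.seed()
// on the R side makes chains reproducible.
// [[Rcpp::export]]
List cpp_rwm_chain(NumericVector y, NumericMatrix X, NumericVector xm,
                   NumericVector gov, bool has_thresh,
                   double tlo, double thi,
                   NumericVector init, NumericVector scale,
                   int n_burn, int n_keep, bool adapt,
                   double prior_sd, double target_acc) {
  const int p = init.size();
  std::vector<double> theta(init.begin(), init.end());
  std::vector<double> ls(p);
  for (int j = 0; j < p; ++j) ls[j] = std::log(scale[j]);

  double lp_cur = log_post(theta, y, X, xm, gov, has_thresh, tlo, thi, prior_sd);
  if (!R_FINITE(lp_cur)) stop("initial state has non-finite posterior density");

  NumericMatrix draws(n_keep, p);
  NumericVector loglik(n_keep);
  IntegerVector acc(p), prop(p);

  const int n_iter = n_burn + n_keep;
  for (int it = 0; it < n_iter; ++it) {
    const bool burn = it < n_burn;
    for (int j = 0; j < p; ++j) {
      double old = theta[j];
      theta[j] = old + std::exp(ls[j]) * R::norm_rand();
      double lp_new = log_post(theta, y, X, xm, gov, has_thresh, tlo, thi,
                               prior_sd);
      bool accept = R_FINITE(lp_new) &&
                    std::log(R::unif_rand()) < lp_new - lp_cur;
      if (accept) {
        lp_cur = lp_new;
      } else {
        theta[j] = old;
      }
      if (burn && adapt) {
        double delta = std::min(0.1, 1.0 / std::sqrt((double)(it + 1)));
        ls[j] += delta * ((accept ? 1.0 : 0.0) - target_acc);
      }
      if (!burn) {
        prop[j] += 1;
        if (accept) acc[j] += 1;
      }
    }
    if (!burn) {
      int r = it - n_burn;
      for (int j = 0; j < p; ++j) draws(r, j) = theta[j];
      loglik[r] = log_lik(theta, y, X, xm, gov, has_thresh);
    }
  }

  NumericVector final_scale(p);
  for (int j = 0; j < p; ++j) final_scale[j] = std::exp(ls[j]);
  return List::create(_["draws"] = draws, _["loglik"] = loglik,
                      _["accepted"] = acc, _["proposed"] = prop,
                      _["scale"] = final_scale);
}
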