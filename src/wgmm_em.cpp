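// Weighted-EM core for Gaussian mixtures. Initialisation, seeding and model
// selection live in R; this is only the numeric inner loop.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void component_logdens(const mat& X, const rowvec& mu, const mat& cov,
                              vec& out) {
  const double d = (double)X.n_cols;
  mat ch;
  if (!chol(ch, cov, "lower")) Rcpp::stop("covariance not positive definite");
  mat diff = X.each_row() - mu;
  mat z = solve(trimatl(ch), diff.t());
  vec q = sum(square(z), 0).t();
  double ldet = accu(log(ch.diag()));
  out = -0.5 * q - ldet - 0.5 * d * std::log(2.0 * M_PI);
}

// [[Rcpp::export]]
Rcpp::List wgmm_em_cpp(const arma::mat& X, const arma::vec& w,
                       arma::mat means, arma::cube covs, arma::vec mix,
                       double reg, int max_iter, double tol) {
  const uword n = X.n_rows;
  const uword k = means.n_rows;
  mat lcomp(n, k);
  vec tmp(n);
  std::vector<double> trace;
  double prev = -datum::inf;
  int iter = 0;
  while (true) {
    ++iter;
    for (uword j = 0; j < k; ++j) {
      component_logdens(X, means.row(j), covs.slice(j), tmp);
      lcomp.col(j) = tmp + std::log(std::max(mix(j), 1e-300));
    }
    vec mx = max(lcomp, 1);
    vec lf = mx + log(sum(exp(lcomp.each_col() - mx), 1));
    double ll = dot(w, lf);
    trace.push_back(ll);
    mat resp = exp(lcomp.each_col() - lf);
    mat wr = resp.each_col() % w;
    rowvec nk = sum(wr, 0);
    nk.transform([](double v) { return std::max(v, 1e-300); });
    mix = nk.t() / accu(nk);
    for (uword j = 0; j < k; ++j) {
      rowvec mu = (wr.col(j).t() * X) / nk(j);
      mat diff = X.each_row() - mu;
      mat c = (diff.each_col() % wr.col(j)).t() * diff / nk(j);
      c.diag() += reg;
      means.row(j) = mu;
      covs.slice(j) = c;
    }
    if (iter >= max_iter) break;
    if (std::isfinite(prev) && std::abs(ll - prev) <= tol * (std::abs(prev) + 1e-12))
      break;
    prev = ll;
  }
  return Rcpp::List::create(
    Rcpp::Named("means") = means,
    Rcpp::Named("covs") = covs,
    Rcpp::Named("mix") = mix,
    Rcpp::Named("loglik_trace") = trace,
    Rcpp::Named("n_iter") = iter);
}

// [[Rcpp::export]]
arma::vec wgmm_logdensity_cpp(const arma::mat& X, const arma::mat& means,
                              const arma::cube& covs, const arma::vec& mix) {
  const uword n = X.n_rows;
  const uword k = means.n_rows;
  mat lcomp(n, k);
  vec tmp(n);
  for (uword j = 0; j < k; ++j) {
    component_logdens(X, means.row(j), covs.slice(j), tmp);
    lcomp.col(j) = tmp + std::log(std::max(mix(j), 1e-300));
  }
  vec mx = max(lcomp, 1);
  return mx + log(sum(exp(lcomp.each_col() - mx), 1));
}
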