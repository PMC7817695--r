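// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Minimum-volume-ellipsoid subset search. Candidate ellipsoids are grown
// from (p+1)-point elemental subsets: each subset's mean/covariance define a
// shape, the ellipsoid is inflated to cover h points, and its volume is
// proportional to m^p * sqrt(det(S)) where m^2 is the h-th smallest squared
// Mahalanobis distance. Subsets are drawn with R's RNG (set.seed applies);
// when the number of elemental subsets is at most `nsamp` the search is
// exhaustive. Returns the squared distances (shape metric) of the best
// candidate, from which the caller extracts the h-point subset.
// [[Rcpp::export(name = ".mve_search")]]
List mve_search(const arma::mat& X, const int h, const int nsamp) {
  const int n = X.n_rows, p = X.n_cols, m = p + 1;
  double best = R_PosInf;
  arma::vec bestd2(n, arma::fill::value(R_PosInf));
  int tried = 0, valid = 0;

  // decide exhaustive vs sampled
  double ncomb = 1.0;
  for (int i = 0; i < m; ++i) ncomb *= (double)(n - i) / (i + 1);
  const bool exhaustive = (ncomb <= (double)nsamp);

  std::vector<int> comb(m);
  for (int i = 0; i < m; ++i) comb[i] = i;
  arma::uvec idx(m);
  const long budget = exhaustive ? (long)std::ceil(ncomb) : nsamp;

  for (long it = 0; it < budget; ++it) {
    if (exhaustive) {
      for (int i = 0; i < m; ++i) idx[i] = comb[i];
    } else {
      // R RNG draw without replacement
      IntegerVector s = Rcpp::sample(n, m, false);
      for (int i = 0; i < m; ++i) idx[i] = s[i] - 1;
    }
    ++tried;
    arma::mat Xs = X.rows(idx);
    arma::rowvec mu = arma::mean(Xs, 0);
    arma::mat S = arma::cov(Xs);
    arma::mat R;
    bool ok = arma::chol(R, S);
    if (ok) {
      double ld = 2.0 * arma::sum(arma::log(R.diag()));
      // squared Mahalanobis distances of all points under (mu, S)
      arma::mat C = X.each_row() - mu;
      arma::mat Z = arma::solve(arma::trimatl(R.t()), C.t());
      arma::vec d2 = arma::sum(arma::square(Z), 0).t();
      arma::vec ds = arma::sort(d2);
      double m2 = ds[h - 1];
      if (m2 > 0) {
        ++valid;
        double crit = ld + p * std::log(m2);
        if (crit < best) { best = crit; bestd2 = d2; }
      }
    }
    if (exhaustive) {  // next combination
      int i = m - 1;
      while (i >= 0 && comb[i] == n - m + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < m; ++j) comb[j] = comb[j - 1] + 1;
    }
  }
  return List::create(_["d2"] = bestd2, _["crit"] = best,
                      _["n_valid"] = valid, _["n_tried"] = tried,
                      _["exhaustive"] = exhaustive);
}
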