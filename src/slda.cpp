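// Searchlight LDA cross-decoding inner loop.
// For each searchlight, build the pooled within-class covariance from the
// class-centered training matrix restricted to the neighborhood's voxels,
// shrink it toward a scaled identity, solve for the discriminant, and record
// the fraction of test trials falling on the positive side of the midpoint
// boundary.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// xc: class-centered training matrix (n x V); xtest: test matrix (m x V);
// mdiff = mu_pos - mu_neg; mid = (mu_pos + mu_neg) / 2 (length V);
// nb: n_voxels x n_centers matrix of 0-based voxel indices; df = n - 2.
// [[Rcpp::export]]
arma::vec slda_fractions(const arma::mat& xc, const arma::mat& xtest,
                         const arma::vec& mdiff, const arma::vec& mid,
                         const arma::imat& nb, double lambda, double df) {
  const arma::uword n_centers = nb.n_cols;
  const arma::uword k = nb.n_rows;
  arma::vec out(n_centers);
  arma::uvec idx(k);
  for (arma::uword j = 0; j < n_centers; ++j) {
    for (arma::uword i = 0; i < k; ++i) idx[i] = (arma::uword) nb(i, j);
    arma::mat xs = xc.cols(idx);
    arma::mat s = (xs.t() * xs) / df;
    s.diag() += lambda * arma::mean(s.diag());
    arma::vec w;
    bool ok = arma::solve(w, s, mdiff.elem(idx),
                          arma::solve_opts::likely_sympd);
    if (!ok) {
      out[j] = arma::datum::nan;
      continue;
    }
    arma::vec scores = xtest.cols(idx) * w - arma::dot(w, mid.elem(idx));
    out[j] = (double) arma::sum(scores > 0) / (double) scores.n_elem;
  }
  return out;
}
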