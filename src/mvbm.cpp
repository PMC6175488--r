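// Pruning-pass profile likelihood for multivariate Brownian motion on a tree.
//
// The model: tip values X (n x p) are MVN with covariance kron(Sigma, C),
// where C_ij is the shared root-to-tip path length of tips i and j after
// per-edge rate scaling. alpha (phylogenetic mean) and Sigma (per-unit-time
// trait covariance) are profiled out at their conditional ML values.
// A single postorder sweep (Felsenstein contrasts) yields the GLS mean,
// the contrast cross-product matrix S = (X-1a)' C^-1 (X-1a) and log|C|
// without forming any dense n x n matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// edge: (E x 2) 1-based node indices (parent, child) in postorder
// lens:  rate-scaled branch lengths, same order as edge rows
// X:     tip traits, row i = tip with node index i (1..ntip)
// Returns loglik = -Inf (with ok = false) when C is singular or the
// profiled Sigma is not positive definite.
// [[Rcpp::export]]
List mvbm_pruning(const arma::imat& edge, const arma::vec& lens,
                  const arma::mat& X, const int ntip) {
  const int E = edge.n_rows;
  const int p = X.n_cols;
  const int M = ntip + (E - ntip) + 1;  // total nodes (binary or not)

  arma::mat xhat(M, p, arma::fill::zeros);
  arma::vec vv(M, arma::fill::zeros);
  arma::ivec seen(M, arma::fill::zeros);

  xhat.rows(0, ntip - 1) = X;

  arma::mat S(p, p, arma::fill::zeros);
  double logdetC = 0.0;
  int ncontr = 0;
  bool ok = true;

  for (int e = 0; e < E; ++e) {
    const int par = edge(e, 0) - 1;
    const int chi = edge(e, 1) - 1;
    const double vc = vv(chi) + lens(e);
    if (!seen(par)) {
      xhat.row(par) = xhat.row(chi);
      vv(par) = vc;
      seen(par) = 1;
    } else {
      const double vs = vv(par) + vc;
      if (vs <= 0.0) { ok = false; break; }
      const arma::rowvec u = xhat.row(par) - xhat.row(chi);
      S += (u.t() * u) / vs;
      logdetC += std::log(vs);
      ++ncontr;
      xhat.row(par) = (vc * xhat.row(par) + vv(par) * xhat.row(chi)) / vs;
      vv(par) = vv(par) * vc / vs;
    }
  }

  const int root = edge(E - 1, 0) - 1;
  double loglik = -arma::datum::inf;
  arma::mat sigma(p, p, arma::fill::zeros);
  arma::rowvec alpha(p, arma::fill::zeros);

  if (ok && vv(root) > 0.0) {
    logdetC += std::log(vv(root));
    alpha = xhat.row(root);
    sigma = S / static_cast<double>(ntip);
    double ldS, signS;
    const bool inv_ok = arma::log_det(ldS, signS, sigma);
    if (inv_ok && signS > 0.0) {
      const double n = static_cast<double>(ntip);
      loglik = -0.5 * n * p * std::log(2.0 * arma::datum::pi)
               - 0.5 * p * logdetC
               - 0.5 * n * ldS
               - 0.5 * n * p;
    } else {
      ok = false;
    }
  } else {
    ok = false;
  }

  return List::create(_["loglik"] = loglik,
                      _["sigma"] = sigma,
                      _["alpha"] = arma::conv_to<arma::vec>::from(alpha),
                      _["logdetC"] = logdetC,
                      _["ncontrasts"] = ncontr,
                      _["ok"] = ok);
}

// Fast path used inside the MCMC: loglik only.
// [[Rcpp::export]]
double mvbm_pruning_ll(const arma::imat& edge, const arma::vec& lens,
                       const arma::mat& X, const int ntip) {
  List res = mvbm_pruning(edge, lens, X, ntip);
  return as<double>(res["loglik"]);
}
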