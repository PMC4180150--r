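// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Site likelihoods for one rate class by Felsenstein pruning.
// U, lambda, sq: eigen machinery of the symmetrized GY rate matrix
// (P(t) = diag(1/sq) U diag(exp(lambda t)) U' diag(sq)); child/parent:
// postorder edge lists (1-based node ids, tips 1..ntip, root = ntip+1);
// tlen: per-edge branch lengths (already scaled); patterns: ntip x npat
// codon indices (1-based, 0 = missing).
// [[Rcpp::export]]
arma::rowvec cpp_class_site_lik(const arma::mat& U, const arma::vec& lambda,
                                const arma::vec& sq, const arma::vec& pi,
                                const IntegerVector& child,
                                const IntegerVector& parent,
                                const arma::vec& tlen,
                                const IntegerMatrix& patterns,
                                int n_nodes, int root) {
  const int ntip = patterns.nrow();
  const int npat = patterns.ncol();
  const int n = U.n_rows;
  std::vector<arma::mat> partial(n_nodes + 1);
  std::vector<bool> started(n_nodes + 1, false);
  arma::vec invsq = 1.0 / sq;
  for (int e = 0; e < child.size(); ++e) {
    int ch = child[e], pa = parent[e];
    arma::mat E = U.each_row() % arma::exp(lambda.t() * tlen[e]);
    arma::mat P = E * U.t();
    P = (P.each_col() % invsq).eval().each_row() % sq.t();
    P.elem(arma::find(P < 0)).zeros();
    arma::mat down(n, npat);
    if (ch <= ntip) {
      arma::vec rowsum = arma::sum(P, 1);         // missing data at the tip
      for (int s = 0; s < npat; ++s) {
        int obs = patterns(ch - 1, s);
        if (obs > 0) down.col(s) = P.col(obs - 1);  // P[x -> observed codon]
        else down.col(s) = rowsum;
      }
    } else {
      down = P * partial[ch];
    }
    if (!started[pa]) { partial[pa] = down; started[pa] = true; }
    else partial[pa] %= down;
  }
  return pi.t() * partial[root];
}
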