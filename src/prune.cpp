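// Fast pruning kernel for the likelihood-only path.
//
// Computes per-pattern log-likelihoods by Felsenstein pruning with per-node
// log-scaling, given per-edge transition matrices. Message passing (outward
// messages, ancestral posteriors, branch curves) stays in R; this kernel is
// only the hot inner loop of the optimizers.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// edge: n_edge x 2 matrix of 1-based (parent, child) in postorder
// children_edges: per-node list of 1-based edge indices (empty for tips)
// parents_order: 1-based internal node ids, children-first order
// P: per-edge S x S transition matrices
// tips: ntip x npat matrix of 1-based tip states
// pi: stationary frequencies (length S)
// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerMatrix edge, List children_edges,
                               IntegerVector parents_order, List P,
                               IntegerMatrix tips, NumericVector pi,
                               int ntip, int nnode) {
  const int npat = tips.ncol();
  const int S = pi.size();
  const int nn = ntip + nnode;
  std::vector<arma::mat> partial(nn + 1);
  std::vector<arma::vec> slog(nn + 1);
  arma::vec zero(npat, arma::fill::zeros);

  for (int oi = 0; oi < parents_order.size(); ++oi) {
    const int nd = parents_order[oi];
    IntegerVector ces = children_edges[nd - 1];
    arma::mat prod;
    arma::vec sl = zero;
    for (int ci = 0; ci < ces.size(); ++ci) {
      const int e = ces[ci] - 1;
      const int ch = edge(e, 1);
      const arma::mat Pe(REAL(VECTOR_ELT(P, e)), S, S, false, true);
      arma::mat Me(S, npat);
      if (ch <= ntip) {
        // tip child: select columns of P by observed state
        for (int s = 0; s < npat; ++s) {
          Me.col(s) = Pe.col(tips(ch - 1, s) - 1);
        }
      } else {
        Me = Pe * partial[ch];
        sl += slog[ch];
      }
      if (ci == 0) prod = Me; else prod %= Me;
    }
    // per-node scaling by column sums (any positive factor is exact)
    arma::rowvec cs = arma::sum(prod, 0);
    for (int s = 0; s < npat; ++s) {
      if (!(cs[s] > 0)) stop("numerical error: zero partial likelihood at pattern %d", s + 1);
      prod.col(s) /= cs[s];
      sl[s] += std::log(cs[s]);
    }
    partial[nd] = prod;
    slog[nd] = sl;
  }
  const int root = ntip + 1;
  const arma::vec piv(pi.begin(), S, false, true);
  arma::rowvec lik = piv.t() * partial[root];
  NumericVector out(npat);
  for (int s = 0; s < npat; ++s) out[s] = std::log(lik[s]) + slog[root][s];
  return out;
}
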