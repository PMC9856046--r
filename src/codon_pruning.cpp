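// Felsenstein pruning over the 61 sense codons, one pass per site class.
// The rate matrices are time-reversible, so each is symmetrized with the
// equilibrium frequencies and exponentiated through a symmetric eigen
// decomposition; transition matrices are then recomposed per branch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// edge: (nedge x 2) 1-based node ids in postorder (children before parents),
//       tips are nodes 1..ntip, the root is node ntip+1 (ape convention)
// tipL: cube n_states x nsites x ntip of leaf partial likelihoods
// Qs:   list of n_states x n_states rate matrices (rows sum to zero)
// pi:   equilibrium frequencies shared by all classes
// returns: (n_class x nsites) per-site log-likelihoods, one row per class
// [[Rcpp::export]]
arma::mat class_site_loglik_cpp(const arma::imat& edge,
                                const arma::vec& edge_len,
                                int ntip, int nnode,
                                const arma::cube& tipL,
                                const Rcpp::List& Qs,
                                const arma::vec& pi) {
  const int nstate = tipL.n_rows;
  const int nsites = tipL.n_cols;
  const int K = Qs.size();
  const int nedge = edge.n_rows;
  const int ntot = ntip + nnode;

  vec sq = sqrt(pi);
  vec isq = 1.0 / sq;
  mat out(K, nsites);

  for (int k = 0; k < K; ++k) {
    mat Q = Rcpp::as<mat>(Qs[k]);
    mat S = (Q.each_col() % sq).eval();
    S.each_row() %= isq.t();
    S = 0.5 * (S + S.t());
    vec eval;
    mat evec;
    if (!eig_sym(eval, evec, S)) {
      Rcpp::stop("eigen decomposition of a class rate matrix failed");
    }
    mat V = evec.each_col() % isq;   // D^{-1/2} U
    mat W = evec.t();
    W.each_row() %= sq.t();          // U' D^{1/2}

    cube part(nstate, nsites, ntot);
    std::vector<char> init(ntot, 0);
    for (int t = 0; t < ntip; ++t) {
      part.slice(t) = tipL.slice(t);
      init[t] = 1;
    }
    for (int e = 0; e < nedge; ++e) {
      int parent = edge(e, 0) - 1;
      int child  = edge(e, 1) - 1;
      if (!init[child]) Rcpp::stop("edge matrix is not in postorder");
      vec ex = exp(eval * edge_len(e));
      mat wl = W * part.slice(child);
      wl.each_col() %= ex;
      mat contrib = V * wl;
      contrib.clamp(0.0, datum::inf);  // clear tiny negative recomposition error
      if (!init[parent]) {
        part.slice(parent) = contrib;
        init[parent] = 1;
      } else {
        part.slice(parent) %= contrib;
      }
    }
    rowvec sitelik = pi.t() * part.slice(ntip);  // root = node ntip+1
    out.row(k) = log(sitelik);
  }
  return out;
}
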