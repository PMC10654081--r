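#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted between-community mean nearest taxon distance for a
// set of sample pairs, under an optional permutation of tip identities.
//
// D    : taxa x taxa cophenetic distance matrix (tree tip order)
// X    : taxa x samples relative abundances, rows aligned with D
// pres : per-sample integer vectors of 0-based indices of taxa present
// pairs: n_pairs x 2, 0-based sample indices
// perm : 0-based permutation mapping table row i -> tip perm[i]
//
// For each sample m involved in any pair, v_m[i] = min_{j in pres[m]}
// D(perm[i], perm[j]) is the nearest-taxon distance from taxon i into
// sample m; shared taxa give 0. Then
//   betaMNTD(k,m) = 0.5 * ( sum_{i in pres[k]} f_ik * v_m[i]
//                         + sum_{i in pres[m]} f_im * v_k[i] )
// with f the within-sample relative abundances (columns of X renormalized
// over present taxa by the caller).
// [[Rcpp::export]]
NumericVector mntd_pairs(const NumericMatrix& D, const NumericMatrix& X,
                         const List& pres, const IntegerMatrix& pairs,
                         const IntegerVector& perm) {
  const int T = D.nrow();
  const int S = X.ncol();
  const int P = pairs.nrow();

  std::vector<bool> needed(S, false);
  for (int p = 0; p < P; ++p) {
    needed[pairs(p, 0)] = true;
    needed[pairs(p, 1)] = true;
  }

  // nearest-taxon distance from every taxon into each needed sample
  std::vector<std::vector<double>> v(S);
  for (int s = 0; s < S; ++s) {
    if (!needed[s]) continue;
    IntegerVector ps = pres[s];
    if (ps.size() == 0) stop("sample with no tree-resident taxa");
    v[s].assign(T, R_PosInf);
    for (int jj = 0; jj < ps.size(); ++jj) {
      const int tip_j = perm[ps[jj]];
      const double* col = &D(0, tip_j);
      std::vector<double>& vs = v[s];
      for (int i = 0; i < T; ++i) {
        const double d = col[perm[i]];
        if (d < vs[i]) vs[i] = d;
      }
    }
  }

  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    const int k = pairs(p, 0), m = pairs(p, 1);
    IntegerVector pk = pres[k], pm = pres[m];
    double a = 0.0, b = 0.0;
    for (int ii = 0; ii < pk.size(); ++ii)
      a += X(pk[ii], k) * v[m][pk[ii]];
    for (int ii = 0; ii < pm.size(); ++ii)
      b += X(pm[ii], m) * v[k][pm[ii]];
    out[p] = 0.5 * (a + b);
  }
  return out;
}
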