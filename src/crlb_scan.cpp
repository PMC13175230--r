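#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exhaustive scan over multisets (combinations with repetition) of n_free
// candidate b-values, minimizing the summed-uncertainty design cost averaged
// over the prior grid.
//
// info:   4 x 4 x (npts * ngrid) cube; single-measurement Fisher
//         contribution of candidate b j under prior point p at slice
//         p * ngrid + j.
// jfixed: 4 x 4 x npts cube; Fisher information of the always-included
//         fixed b-values under each prior point.
// divis:  npts x 3 matrix; divisors turning sqrt-CRLB diagonals into the
//         cost terms (1 for absolute sigma_f, D and Dstar for the relative
//         terms). Column order: f, D, Dstar.
//
// Parameter order inside the matrices: S0, f, D, Dstar.
//
// Returns the lexicographically smallest cost-minimizing index multiset
// (1-based) and its cost. Enumeration is in lexicographic order with a
// strict improvement rule, so ties resolve to the smallest multiset and the
// result does not depend on any randomization.
// [[Rcpp::export]]
List crlb_scan(const arma::cube& info, const arma::cube& jfixed,
               const arma::mat& divis, int ngrid, int n_free) {
  const int npts = jfixed.n_slices;
  std::vector<int> idx(n_free, 0);
  std::vector<int> best(n_free, -1);
  double best_cost = arma::datum::inf;
  arma::mat J(4, 4), C(4, 4);

  bool done = (ngrid == 0 || n_free == 0);
  while (!done) {
    double total = 0.0;
    bool feasible = true;
    for (int p = 0; p < npts && feasible; ++p) {
      J = jfixed.slice(p);
      for (int k = 0; k < n_free; ++k)
        J += info.slice(p * ngrid + idx[k]);
      if (!arma::inv_sympd(C, J)) {
        feasible = false;
        break;
      }
      if (C(1, 1) < 0 || C(2, 2) < 0 || C(3, 3) < 0) {
        feasible = false;
        break;
      }
      total += std::sqrt(C(1, 1)) / divis(p, 0) +
               std::sqrt(C(2, 2)) / divis(p, 1) +
               std::sqrt(C(3, 3)) / divis(p, 2);
    }
    if (feasible) {
      double cost = total / npts;
      if (cost < best_cost) {
        best_cost = cost;
        best = idx;
      }
    }
    // next nondecreasing index vector (multiset odometer)
    int k = n_free - 1;
    while (k >= 0 && idx[k] == ngrid - 1) --k;
    if (k < 0) {
      done = true;
    } else {
      int v = idx[k] + 1;
      for (int j = k; j < n_free; ++j) idx[j] = v;
    }
  }

  IntegerVector out(n_free);
  for (int k = 0; k < n_free; ++k) out[k] = best[k] + 1;
  return List::create(_["indices"] = out, _["cost"] = best_cost);
}
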