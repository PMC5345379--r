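#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Felsenstein pruning for one group of characters sharing a state count k and
// rate matrix (via its symmetric eigendecomposition Q = U diag(lambda) U^T).
//
// edge:    (nedge x 2) 1-based ape edge matrix in postorder (child rows before
//          any row where that child appears as parent).
// elen:    edge lengths (expected changes per character).
// tipPart: leaf partial likelihoods, dim (k, ncol, ntip): 1 on states in the
//          observed state-set, 0 elsewhere.
// rates:   per-category rate multipliers (mean 1).
//
// Returns an (ncat x ncol) matrix of per-category log-likelihoods under the
// uniform stationary distribution pi = 1/k. Partials are rescaled per node
// and column, so results are stable for deep trees.
// [[Rcpp::export(name = ".mk_prune_group_cpp")]]
NumericMatrix mk_prune_group(IntegerMatrix edge, NumericVector elen,
                             int ntip, int nnodes_total,
                             NumericVector tipPart, int k, int ncol,
                             NumericMatrix U, NumericVector lambda,
                             NumericVector rates) {
  const int nedge = edge.nrow();
  const int ncat = rates.size();
  NumericMatrix out(ncat, ncol);
  std::vector<double> partial((size_t)nnodes_total * k * ncol);
  std::vector<double> logscale((size_t)nnodes_total * ncol);
  std::vector<double> P((size_t)k * k), tmp((size_t)k);

  for (int r = 0; r < ncat; ++r) {
    const double rate = rates[r];
    // init: tips from tipPart, internals to 1, logscale 0
    for (int n = 0; n < nnodes_total; ++n) {
      double *pn = &partial[(size_t)n * k * ncol];
      if (n < ntip) {
        // tipPart is an R array dim (k, ncol, ntip), column-major
        const double *tp = &tipPart[(size_t)n * k * ncol];
        for (int j = 0; j < ncol; ++j)
          for (int i = 0; i < k; ++i)
            pn[(size_t)i * ncol + j] = tp[(size_t)j * k + i];
      } else {
        std::fill(pn, pn + (size_t)k * ncol, 1.0);
      }
      std::fill(&logscale[(size_t)n * ncol],
                &logscale[(size_t)n * ncol] + ncol, 0.0);
    }
    for (int e = 0; e < nedge; ++e) {
      const int p = edge(e, 0) - 1;
      const int c = edge(e, 1) - 1;
      const double t = elen[e] * rate;
      // P = U diag(exp(lambda * t)) U^T  (U orthonormal, Q symmetric)
      for (int i = 0; i < k; ++i) {
        for (int j = 0; j < k; ++j) {
          double s = 0.0;
          for (int a = 0; a < k; ++a)
            s += U(i, a) * std::exp(lambda[a] * t) * U(j, a);
          P[(size_t)i * k + j] = s < 0.0 ? 0.0 : s;
        }
      }
      double *pc = &partial[(size_t)c * k * ncol];
      double *pp = &partial[(size_t)p * k * ncol];
      double *lc = &logscale[(size_t)c * ncol];
      double *lp = &logscale[(size_t)p * ncol];
      for (int j = 0; j < ncol; ++j) {
        double mx = 0.0;
        for (int i = 0; i < k; ++i) {
          double s = 0.0;
          for (int a = 0; a < k; ++a)
            s += P[(size_t)i * k + a] * pc[(size_t)a * ncol + j];
          tmp[i] = s;
        }
        for (int i = 0; i < k; ++i) {
          double v = pp[(size_t)i * ncol + j] * tmp[i];
          pp[(size_t)i * ncol + j] = v;
          if (v > mx) mx = v;
        }
        lp[j] += lc[j];
        if (mx > 0.0 && mx < 1e-100) {
          for (int i = 0; i < k; ++i) pp[(size_t)i * ncol + j] /= mx;
          lp[j] += std::log(mx);
        }
      }
    }
    const int root = edge(nedge - 1, 0) - 1;
    const double *pr = &partial[(size_t)root * k * ncol];
    const double *lr = &logscale[(size_t)root * ncol];
    for (int j = 0; j < ncol; ++j) {
      double s = 0.0;
      for (int i = 0; i < k; ++i) s += pr[(size_t)i * ncol + j];
      out(r, j) = std::log(s / k) + lr[j];
    }
  }
  return out;
}
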