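// Batch evolution of the 4-state linear mutation ODE dC/dt = M C for
// ensembles of rate sets. The generator matrix M uses the column-as-source
// convention (M[u][s] = k_{s->u}, columns sum to zero), and compositions are
// propagated with the matrix exponential C(t) = expm(M t) C(0), which is the
// exact solution of the linear system.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Rate columns in the package's canonical alphabetical label order:
// AC AG AT CA CG CT GA GC GT TA TC TG  (bases ordered A, C, G, T)
static const int SRC[12] = {0, 0, 0, 1, 1, 1, 2, 2, 2, 3, 3, 3};
static const int TGT[12] = {1, 2, 3, 0, 2, 3, 0, 1, 3, 0, 1, 2};

static arma::mat generator(const arma::rowvec& k) {
  arma::mat M(4, 4, arma::fill::zeros);
  for (int e = 0; e < 12; ++e) {
    M(TGT[e], SRC[e]) += k(e);
    M(SRC[e], SRC[e]) -= k(e);
  }
  return M;
}

// [[Rcpp::export]]
arma::mat cpp_rate_matrix(const arma::rowvec& rates) {
  return generator(rates);
}

// Final compositions of n systems at a single time t.
// rates: n x 12; c0: n x 4 or 1 x 4 (recycled). Returns n x 4.
// [[Rcpp::export]]
arma::mat cpp_final_compositions(const arma::mat& rates, const arma::mat& c0,
                                 const double t) {
  const arma::uword n = rates.n_rows;
  arma::mat out(n, 4);
  for (arma::uword s = 0; s < n; ++s) {
    arma::mat P = arma::expmat(generator(rates.row(s)) * t);
    arma::vec c = (c0.n_rows == 1) ? c0.row(0).t() : c0.row(s).t();
    out.row(s) = (P * c).t();
  }
  return out;
}

// Full trajectories of n systems on a shared time grid.
// Returns a 4 x m x n cube (base, time, system).
// [[Rcpp::export]]
arma::cube cpp_batch_trajectories(const arma::mat& rates, const arma::mat& c0,
                                  const arma::vec& times) {
  const arma::uword n = rates.n_rows, m = times.n_elem;
  arma::cube out(4, m, n);
  for (arma::uword s = 0; s < n; ++s) {
    arma::mat M = generator(rates.row(s));
    arma::vec c = (c0.n_rows == 1) ? c0.row(0).t() : c0.row(s).t();
    // step with increments so each expm spans only one grid interval
    arma::vec cur = c;
    double prev = 0.0;
    for (arma::uword ti = 0; ti < m; ++ti) {
      const double dt = times(ti) - prev;
      if (dt != 0.0) cur = arma::expmat(M * dt) * cur;
      prev = times(ti);
      out.slice(s).col(ti) = cur;
    }
  }
  return out;
}

// Composition of one system at one time (used for bisection refinement).
// [[Rcpp::export]]
arma::vec cpp_composition_at(const arma::rowvec& rates, const arma::vec& c0,
                             const double t) {
  return arma::expmat(generator(rates) * t) * c0;
}
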