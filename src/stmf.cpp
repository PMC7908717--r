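#include <Rcpp.h>
using namespace Rcpp;

// Greatest subsolution of U (x) X = R, column-wise, skipping masked entries:
// V(k, j) = min over given i of (R(i, j) - U(i, k)).
// [[Rcpp::export]]
NumericMatrix cpp_solve_right(const NumericMatrix& U, const NumericMatrix& R,
                              const LogicalMatrix& given) {
  const int m = U.nrow(), r = U.ncol(), n = R.ncol();
  NumericMatrix V(r, n);
  for (int j = 0; j < n; ++j) {
    for (int k = 0; k < r; ++k) {
      double best = R_PosInf;
      for (int i = 0; i < m; ++i) {
        if (given(i, j)) {
          double cand = R(i, j) - U(i, k);
          if (cand < best) best = cand;
        }
      }
      if (best == R_PosInf)
        stop("column %d of R has no given entries", j + 1);
      V(k, j) = best;
    }
  }
  return V;
}

// Mirror solve for Y (x) V = R: U(i, k) = min over given j of (R(i, j) - V(k, j)).
// [[Rcpp::export]]
NumericMatrix cpp_solve_left(const NumericMatrix& V, const NumericMatrix& R,
                             const LogicalMatrix& given) {
  const int r = V.nrow(), n = V.ncol(), m = R.nrow();
  NumericMatrix U(m, r);
  for (int i = 0; i < m; ++i) {
    for (int k = 0; k < r; ++k) {
      double best = R_PosInf;
      for (int j = 0; j < n; ++j) {
        if (given(i, j)) {
          double cand = R(i, j) - V(k, j);
          if (cand < best) best = cand;
        }
      }
      if (best == R_PosInf)
        stop("row %d of R has no given entries", i + 1);
      U(i, k) = best;
    }
  }
  return U;
}

// b-norm of R - U (x) V over the given entries of R.
static double masked_residual_bnorm(const NumericMatrix& R,
                                    const LogicalMatrix& given,
                                    const NumericMatrix& U,
                                    const NumericMatrix& V) {
  const int m = R.nrow(), n = R.ncol(), r = U.ncol();
  double total = 0.0;
  for (int j = 0; j < n; ++j) {
    for (int i = 0; i < m; ++i) {
      if (!given(i, j)) continue;
      double rec = R_NegInf;
      for (int k = 0; k < r; ++k) {
        double cand = U(i, k) + V(k, j);
        if (cand > rec) rec = cand;
      }
      total += std::fabs(R(i, j) - rec);
    }
  }
  return total;
}

// [[Rcpp::export]]
double cpp_masked_residual_bnorm(const NumericMatrix& R,
                                 const LogicalMatrix& given,
                                 const NumericMatrix& U,
                                 const NumericMatrix& V) {
  return masked_residual_bnorm(R, given, U, V);
}

// Smallest index k maximizing U(i, k) + V(k, j): the active term of the
// (max,+) reconstruction at (i, j); ties broken toward the smallest k for
// determinism.
static int active_index(const NumericMatrix& U, const NumericMatrix& V,
                        int i, int j) {
  const int r = U.ncol();
  int kstar = 0;
  double best = U(i, 0) + V(0, j);
  for (int k = 1; k < r; ++k) {
    double cand = U(i, k) + V(k, j);
    if (cand > best) { best = cand; kstar = k; }
  }
  return kstar;
}

// One entry update through the left factor (ULF): adapt the active entry of
// row i of U so the reconstruction at (i, j) can attain R(i, j), then
// recompute V as the greatest subsolution. Returns the candidate error and
// fills U2/V2.
static double ulf_candidate(int i, int j,
                            const NumericMatrix& U, const NumericMatrix& V,
                            const NumericMatrix& R, const LogicalMatrix& given,
                            NumericMatrix& U2, NumericMatrix& V2) {
  U2 = clone(U);
  int kstar = active_index(U, V, i, j);
  U2(i, kstar) = R(i, j) - V(kstar, j);
  V2 = cpp_solve_right(U2, R, given);
  return masked_residual_bnorm(R, given, U2, V2);
}

// Mirror update through the right factor (URF): adapt the active entry of
// column j of V, then recompute U as the greatest subsolution.
static double urf_candidate(int i, int j,
                            const NumericMatrix& U, const NumericMatrix& V,
                            const NumericMatrix& R, const LogicalMatrix& given,
                            NumericMatrix& U2, NumericMatrix& V2) {
  V2 = clone(V);
  int kstar = active_index(U, V, i, j);
  V2(kstar, j) = R(i, j) - U(i, kstar);
  U2 = cpp_solve_left(V2, R, given);
  return masked_residual_bnorm(R, given, U2, V2);
}

// [[Rcpp::export]]
List cpp_ulf_update(int i, int j, const NumericMatrix& U,
                    const NumericMatrix& V, const NumericMatrix& R,
                    const LogicalMatrix& given) {
  NumericMatrix U2, V2;
  double err = ulf_candidate(i - 1, j - 1, U, V, R, given, U2, V2);
  return List::create(_["U"] = U2, _["V"] = V2, _["error"] = err);
}

// [[Rcpp::export]]
List cpp_urf_update(int i, int j, const NumericMatrix& U,
                    const NumericMatrix& V, const NumericMatrix& R,
                    const LogicalMatrix& given) {
  NumericMatrix U2, V2;
  double err = urf_candidate(i - 1, j - 1, U, V, R, given, U2, V2);
  return List::create(_["U"] = U2, _["V"] = V2, _["error"] = err);
}

// Full fitting loop. Starting from U0, V is the greatest subsolution of
// U0 (x) X = R; then up to max_iter sweeps visit the given entries in
// row-major order, trying one factor-entry update per entry (ULF first, then
// URF, or the reverse when urf_first) and accepting a candidate only when the
// training b-norm strictly decreases by more than tol. Stops early after a
// sweep with no accepted update. The error trace holds the objective after
// the initial solve and after each sweep.
// [[Rcpp::export]]
List cpp_stmf_fit(const NumericMatrix& R, const LogicalMatrix& given,
                  const NumericMatrix& U0, int max_iter, double tol,
                  bool urf_first) {
  const int m = R.nrow(), n = R.ncol();
  NumericMatrix U = clone(U0);
  NumericMatrix V = cpp_solve_right(U, R, given);
  double err = masked_residual_bnorm(R, given, U, V);
  std::vector<double> trace;
  trace.push_back(err);

  int sweeps = 0;
  for (int it = 0; it < max_iter; ++it) {
    bool accepted_any = false;
    for (int i = 0; i < m; ++i) {
      for (int j = 0; j < n; ++j) {
        if (!given(i, j)) continue;
        NumericMatrix U2, V2;
        double cand = urf_first
          ? urf_candidate(i, j, U, V, R, given, U2, V2)
          : ulf_candidate(i, j, U, V, R, given, U2, V2);
        if (cand < err - tol) {
          U = U2; V = V2; err = cand; accepted_any = true;
          continue;
        }
        cand = urf_first
          ? ulf_candidate(i, j, U, V, R, given, U2, V2)
          : urf_candidate(i, j, U, V, R, given, U2, V2);
        if (cand < err - tol) {
          U = U2; V = V2; err = cand; accepted_any = true;
        }
      }
    }
    ++sweeps;
    trace.push_back(err);
    if (!accepted_any) break;
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["U"] = U, _["V"] = V,
                      _["error_trace"] = wrap(trace),
                      _["sweeps"] = sweeps);
}
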