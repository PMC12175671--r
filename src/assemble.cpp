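#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/Lapack.h>
#ifndef FCONE
# define FCONE
#endif
#include <vector>

using namespace Rcpp;

// Assemble the leading nkeep x nkeep block of the real normal-equation
// matrix generated by the mask structure factors S.
//
// Row/column layout: full index f (0-based) maps to mode p = f / 2 of the
// full lattice and to the b-unknown when f is even, c when odd. Because the
// lattice ordering is negation-symmetric with the zero mode at the centre,
// the leading M rows/columns are exactly the b/c pairs of the first
// (M - 1) / 2 modes plus the b of the zero mode, i.e. the reduced system.
//
// S is the complex structure-factor array over the extended lattice,
// flattened column-major; evec[p] is the 0-based linear index of full-lattice
// mode p inside the extended array, and off the index of the zero tuple, so
// lin(m + n) = evec[m] + evec[n] - off and lin(m - n) = evec[m] - evec[n] + off.
//
// Block entries (m = row mode, n = column mode, e1 = S[m+n], e2 = S[m-n]):
//   (b,b)  Re(e1) + Re(e2)
//   (b,c) -Im(e1) + Im(e2)
//   (c,b)  Im(e1) + Im(e2)
//   (c,c)  Re(e1) - Re(e2)
// [[Rcpp::export]]
NumericMatrix assemble_block_cpp(ComplexVector S, IntegerVector evec,
                                 int off, int nkeep) {
  const Rcomplex* s = S.begin();
  NumericMatrix out(nkeep, nkeep);
  double* o = out.begin();
  for (int col = 0; col < nkeep; ++col) {
    const int pn = col >> 1;
    const bool col_b = (col & 1) == 0;
    const int en = evec[pn];
    for (int row = 0; row < nkeep; ++row) {
      const int pm = row >> 1;
      const bool row_b = (row & 1) == 0;
      const int em = evec[pm];
      const Rcomplex e1 = s[em + en - off];
      const Rcomplex e2 = s[em - en + off];
      double v;
      if (row_b) {
        v = col_b ? (e1.r + e2.r) : (-e1.i + e2.i);
      } else {
        v = col_b ? (e1.i + e2.i) : (e1.r - e2.r);
      }
      o[(size_t)col * nkeep + row] = v;
    }
  }
  return out;
}

// Full-spectrum symmetric eigendecomposition via LAPACK dsyevd
// (divide and conquer), IN PLACE: X is overwritten with the eigenvectors
// and the eigenvalues are returned ascending. The caller must own X and
// accept its destruction; dsyevd needs a 2n^2-sized scratch buffer, which
// together with the in-place update keeps the peak footprint at roughly
// three matrices for the large 3D systems.
// [[Rcpp::export]]
NumericVector eig_sym_inplace(NumericMatrix X) {
  const int n = X.nrow();
  if (n != X.ncol()) stop("matrix must be square");
  NumericVector vals(n);
  int info = 0;
  int lwork = -1, liwork = -1;
  double wq = 0; int iwq = 0;
  F77_CALL(dsyevd)("V", "L", &n, X.begin(), &n, vals.begin(),
                   &wq, &lwork, &iwq, &liwork, &info FCONE FCONE);
  if (info != 0) stop("dsyevd workspace query failed");
  lwork = (int)wq;
  liwork = iwq;
  std::vector<double> work((size_t)lwork);
  std::vector<int> iwork((size_t)liwork);
  F77_CALL(dsyevd)("V", "L", &n, X.begin(), &n, vals.begin(),
                   work.data(), &lwork, iwork.data(), &liwork,
                   &info FCONE FCONE);
  if (info != 0) stop("dsyevd failed to converge");
  return vals;
}

// Multiply row i by sgn[i], in place (no copy). Used to map AA onto its
// symmetric Gram form and back: the caller owns the matrix and restores it
// by applying the same +/-1 signs again.
// [[Rcpp::export]]
void scale_rows_inplace(NumericMatrix X, NumericVector sgn) {
  const int n = X.nrow(), m = X.ncol();
  if (sgn.size() != n) stop("sign vector length mismatch");
  double* x = X.begin();
  for (int j = 0; j < m; ++j) {
    double* cptr = x + (size_t)j * n;
    for (int i = 0; i < n; ++i) cptr[i] *= sgn[i];
  }
}
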