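#include <Rcpp.h>
using namespace Rcpp;

// Selected inverse (Takahashi equations) of a symmetric positive definite
// matrix C = L L', computed on the sparsity pattern of the Cholesky factor L.
//
// Input: L in compressed sparse column form (Lp, Li, Lx), lower triangular,
// row indices sorted within each column, diagonal entry first implied by
// sortedness.  Output: Zx with the same layout, holding (C^-1)_{ij} for every
// structural (i, j) of L.
//
// Recurrences (columns processed from right to left):
//   Z_jj = (1/L_jj) * (1/L_jj - sum_{k>j} L_kj Z_kj)
//   Z_ij = -(1/L_jj) * sum_{k>j} L_kj Z_(max(i,k), min(i,k)),  i > j
// All referenced entries lie in the factor's pattern (pattern closure of the
// Cholesky factorization), so the recursion is exact, not approximate.

static inline double z_lookup(const int *Lp, const int *Li, const double *Zx,
                              int r, int c) {
  // entry (r, c) with r >= c; binary search among sorted rows of column c
  int lo = Lp[c], hi = Lp[c + 1] - 1;
  while (lo <= hi) {
    int mid = (lo + hi) / 2;
    if (Li[mid] == r) return Zx[mid];
    if (Li[mid] < r) lo = mid + 1; else hi = mid - 1;
  }
  return NA_REAL; // structurally absent (should not happen for a valid factor)
}

// [[Rcpp::export]]
NumericVector cpp_selinv(IntegerVector Lp_, IntegerVector Li_, NumericVector Lx_, int n) {
  const int *Lp = INTEGER(Lp_); const int *Li = INTEGER(Li_);
  const double *Lx = REAL(Lx_);
  NumericVector Z(Lx_.size());
  double *Zx = REAL(Z);
  // scatter workspace: mark[r] = position of row r in the current column
  std::vector<int> mark(n, -1);
  std::vector<double> acc(n, 0.0);
  for (int j = n - 1; j >= 0; --j) {
    int pj0 = Lp[j], pj1 = Lp[j + 1];
    double ljj = Lx[pj0]; // diagonal is the first (smallest row index) entry
    for (int p = pj0 + 1; p < pj1; ++p) { mark[Li[p]] = p; acc[p - pj0] = 0.0; }
    // acc(i) = sum_k L_kj * Z(max(i,k), min(i,k)) over i,k in struct(col j):
    // scan each column k of Z once, pairing entries through the mask
    for (int q = pj0 + 1; q < pj1; ++q) {
      int k = Li[q];
      double lkj = Lx[q];
      for (int t = Lp[k]; t < Lp[k + 1]; ++t) {
        int r = Li[t];
        int p2 = mark[r];
        if (p2 < 0) continue;
        if (r == k) {
          acc[q - pj0] += lkj * Zx[t];
        } else { // r > k, both in struct(col j)
          acc[p2 - pj0] += lkj * Zx[t];
          acc[q - pj0] += Lx[p2] * Zx[t];
        }
      }
    }
    double sdiag = 0.0;
    for (int p = pj0 + 1; p < pj1; ++p) {
      Zx[p] = -acc[p - pj0] / ljj;
      sdiag += Lx[p] * Zx[p];
    }
    Zx[pj0] = (1.0 / ljj - sdiag) / ljj;
    for (int p = pj0 + 1; p < pj1; ++p) mark[Li[p]] = -1;
  }
  return Z;
}

// Look up entries of the selected inverse in ORIGINAL (unpermuted) indexing.
// perm maps original index -> permuted index (0-based).  Entries outside the
// factor pattern come back NA; callers fall back to an exact solve for those.
// [[Rcpp::export]]
NumericVector cpp_selinv_lookup(IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                                IntegerVector perm, IntegerVector rows, IntegerVector cols) {
  const int *Lp = INTEGER(Lp_); const int *Li = INTEGER(Li_);
  const double *Zx = REAL(Zx_);
  int m = rows.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    int r = perm[rows[t]], c = perm[cols[t]];
    if (r < c) std::swap(r, c);
    out[t] = z_lookup(Lp, Li, Zx, r, c);
  }
  return out;
}

// trace(B' Cinv_block) over the structural nonzeros of sparse B (CSC), where
// the block of C^-1 is addressed with row/column offsets: the (a, b) entry of
// B meets C^-1[roff + a, coff + b].  Returns the partial trace plus the list
// of entries that fell outside the factor pattern (normally none).
// [[Rcpp::export]]
List cpp_selinv_trace(IntegerVector Bp_, IntegerVector Bi_, NumericVector Bx_,
                      int roff, int coff,
                      IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                      IntegerVector perm) {
  const int *Bp = INTEGER(Bp_); const int *Bi = INTEGER(Bi_);
  const double *Bx = REAL(Bx_);
  const int *Lp = INTEGER(Lp_); const int *Li = INTEGER(Li_);
  const double *Zx = REAL(Zx_);
  int nb = Bp_.size() - 1;
  double tr = 0.0;
  std::vector<int> miss_r, miss_c;
  std::vector<double> miss_x;
  for (int b = 0; b < nb; ++b) {
    for (int p = Bp[b]; p < Bp[b + 1]; ++p) {
      int a = Bi[p];
      int r = perm[roff + a], c = perm[coff + b];
      if (r < c) std::swap(r, c);
      double z = z_lookup(Lp, Li, Zx, r, c);
      if (ISNAN(z)) {
        miss_r.push_back(roff + a); miss_c.push_back(coff + b); miss_x.push_back(Bx[p]);
      } else {
        tr += Bx[p] * z;
      }
    }
  }
  return List::create(_["trace"] = tr,
                      _["miss_row"] = wrap(miss_r),
                      _["miss_col"] = wrap(miss_c),
                      _["miss_val"] = wrap(miss_x));
}

// Row-wise quadratic forms m_i' C^-1 m_i for a sparse matrix M given in
// row-compressed form (Mp over rows, Mj column indices, Mx values).  Used for
// hat-matrix diagonals: every (j, k) pair within a row's support is a
// structural nonzero of C, hence inside the factor pattern.
// [[Rcpp::export]]
List cpp_rowwise_quadform(IntegerVector Mp_, IntegerVector Mj_, NumericVector Mx_,
                          IntegerVector Lp_, IntegerVector Li_, NumericVector Zx_,
                          IntegerVector perm) {
  const int *Mp = INTEGER(Mp_); const int *Mj = INTEGER(Mj_);
  const double *Mx = REAL(Mx_);
  const int *Lp = INTEGER(Lp_); const int *Li = INTEGER(Li_);
  const double *Zx = REAL(Zx_);
  int n = Mp_.size() - 1;
  NumericVector out(n);
  std::vector<int> miss_rows;
  for (int i = 0; i < n; ++i) {
    double q = 0.0;
    bool ok = true;
    for (int p = Mp[i]; p < Mp[i + 1] && ok; ++p) {
      int pj = perm[Mj[p]];
      for (int s = Mp[i]; s < Mp[i + 1]; ++s) {
        int ps = perm[Mj[s]];
        int r = pj >= ps ? pj : ps, c = pj >= ps ? ps : pj;
        double z = z_lookup(Lp, Li, Zx, r, c);
        if (ISNAN(z)) { ok = false; break; }
        q += Mx[p] * Mx[s] * z;
      }
    }
    if (ok) out[i] = q; else { out[i] = NA_REAL; miss_rows.push_back(i + 1); }
  }
  return List::create(_["q"] = out, _["miss_rows"] = wrap(miss_rows));
}
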