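#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo style algorithm.
// sire/dam are 1-based indices into the topologically ordered pedigree,
// 0 = unknown parent.  Parents must precede offspring.
//
// For animal i, A(i,i) = sum_j L_j^2 d_j over ancestors j, where L is the
// path contribution vector (L_i = 1, L_parent += 0.5 L_child) and d_j is the
// Mendelian sampling variance of j given its parents' inbreeding.
// [[Rcpp::export]]
List cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector f(n), d(n);
  std::vector<double> L(n + 1);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    double dd = 1.0;
    if (s > 0) dd -= 0.25 * (1.0 + f[s - 1]);
    if (m > 0) dd -= 0.25 * (1.0 + f[m - 1]);
    d[i] = dd;
    if (s == 0 || m == 0) { f[i] = 0.0; continue; }
    // back-propagate path coefficients from i to its ancestors
    std::fill(L.begin(), L.begin() + i + 1, 0.0);
    L[i] = 1.0;
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      aii += L[j] * L[j] * d[j];
      int sj = sire[j], mj = dam[j];
      if (sj > 0) L[sj - 1] += 0.5 * L[j];
      if (mj > 0) L[mj - 1] += 0.5 * L[j];
    }
    f[i] = aii - 1.0;
  }
  return List::create(_["f"] = f, _["d"] = d);
}

// Numerator relationship matrix by the tabular method.
// Same index conventions as cpp_inbreeding.  O(n^2) memory: intended for
// desk-scale pedigrees; large evaluations use the sparse inverse instead.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    for (int j = 0; j < i; ++j) {
      double a = 0.0;
      if (s > 0) a += 0.5 * A(j, s - 1);
      if (m > 0) a += 0.5 * A(j, m - 1);
      A(i, j) = a;
      A(j, i) = a;
    }
    double aii = 1.0;
    if (s > 0 && m > 0) aii += 0.5 * A(s - 1, m - 1);
    A(i, i) = aii;
  }
  return A;
}
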