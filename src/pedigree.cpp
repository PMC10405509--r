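#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Mendelian sampling variance coefficients d_i given parental inbreeding.
// sire/dam are 1-based indices into a topologically sorted pedigree, 0 = unknown.
static std::vector<double> mendelian_d(const IntegerVector& sire,
                                       const IntegerVector& dam,
                                       const NumericVector& F) {
  int n = sire.size();
  std::vector<double> d(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    if (s > 0 && m > 0)      d[i] = 0.5  - 0.25 * (F[s - 1] + F[m - 1]);
    else if (s > 0)          d[i] = 0.75 - 0.25 * F[s - 1];
    else if (m > 0)          d[i] = 0.75 - 0.25 * F[m - 1];
    else                     d[i] = 1.0;
  }
  return d;
}

// Meuwissen & Luo (1992) recursion for inbreeding coefficients.
// Processes each animal's ancestor list youngest-first; a parent is only
// visited after all of its descendants' path contributions have been
// accumulated, which the descending index order guarantees in a sorted
// pedigree.
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), L(n, 0.0);
  for (int i = 0; i < n; ++i) {
    int s = sire[i], m = dam[i];
    if (s > 0 && m > 0)      D[i] = 0.5  - 0.25 * (F[s - 1] + F[m - 1]);
    else if (s > 0)          D[i] = 0.75 - 0.25 * F[s - 1];
    else if (m > 0)          D[i] = 0.75 - 0.25 * F[m - 1];
    else                     D[i] = 1.0;
    if (s == 0 || m == 0) { F[i] = 0.0; continue; }
    std::set<int, std::greater<int> > anc;
    L[i] = 1.0;
    anc.insert(i);
    double aii = 0.0;
    while (!anc.empty()) {
      int j = *anc.begin();
      anc.erase(anc.begin());
      double lj = L[j];
      L[j] = 0.0;
      aii += lj * lj * D[j];
      int js = sire[j], jm = dam[j];
      if (js > 0) { if (L[js - 1] == 0.0) anc.insert(js - 1); L[js - 1] += 0.5 * lj; }
      if (jm > 0) { if (L[jm - 1] == 0.0) anc.insert(jm - 1); L[jm - 1] += 0.5 * lj; }
    }
    F[i] = aii - 1.0;
  }
  return F;
}

// A %*% X without forming A, using A = T D T' where a_i = (a_s + a_d)/2 + phi_i.
// X is n x k; returns n x k.
// [[Rcpp::export]]
NumericMatrix a_mult_cpp(IntegerVector sire, IntegerVector dam,
                         NumericVector F, NumericMatrix X) {
  int n = sire.size(), k = X.ncol();
  if (X.nrow() != n) stop("X must have one row per animal");
  std::vector<double> d = mendelian_d(sire, dam, F);
  NumericMatrix out(n, k);
  std::vector<double> t(n);
  for (int c = 0; c < k; ++c) {
    for (int i = 0; i < n; ++i) t[i] = X(i, c);
    // t := T' x  (accumulate children into parents, youngest first)
    for (int i = n - 1; i >= 0; --i) {
      int s = sire[i], m = dam[i];
      if (s > 0) t[s - 1] += 0.5 * t[i];
      if (m > 0) t[m - 1] += 0.5 * t[i];
    }
    for (int i = 0; i < n; ++i) t[i] *= d[i];
    // out := T (D T' x)
    for (int i = 0; i < n; ++i) {
      double v = t[i];
      int s = sire[i], m = dam[i];
      if (s > 0) v += 0.5 * out(s - 1, c);
      if (m > 0) v += 0.5 * out(m - 1, c);
      out(i, c) = v;
    }
  }
  return out;
}

// log|A| = sum(log d_i), used in the restricted likelihood.
// [[Rcpp::export]]
double a_logdet_cpp(IntegerVector sire, IntegerVector dam, NumericVector F) {
  std::vector<double> d = mendelian_d(sire, dam, F);
  double s = 0.0;
  for (size_t i = 0; i < d.size(); ++i) s += std::log(d[i]);
  return s;
}
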