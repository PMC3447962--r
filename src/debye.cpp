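// Debye sum over atom pairs: I(q) = sum_ij g_i(q) g_j(q) sinc(q r_ij)
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_debye")]]
NumericVector cpp_debye(NumericMatrix xyz, NumericMatrix G,
                        NumericVector q) {
  const int n = xyz.nrow(), nq = q.size();
  if (G.ncol() != n || G.nrow() != nq)
    stop("form-factor matrix must be nq x n_atoms");
  NumericVector I(nq);
  // self terms
  for (int iq = 0; iq < nq; ++iq) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += G(iq, i) * G(iq, i);
    I[iq] = s;
  }
  // pair terms
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dx = xyz(i, 0) - xyz(j, 0);
      double dy = xyz(i, 1) - xyz(j, 1);
      double dz = xyz(i, 2) - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int iq = 0; iq < nq; ++iq) {
        double x = q[iq] * r;
        double sinc = (x < 1e-12) ? 1.0 : std::sin(x) / x;
        I[iq] += 2.0 * G(iq, i) * G(iq, j) * sinc;
      }
    }
  }
  return I;
}
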