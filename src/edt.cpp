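#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012): two orthogonal passes of the 1-D lower-envelope
// algorithm. Squared distances between pixel centres are integers, so the
// result is exact in double precision.

static const double EDT_INF = 1e20;

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

//' @name edt_squared
//' @noRd
// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));

  // pass 1: down each column
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = mask(i, j) ? 0.0 : EDT_INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // pass 2: along each row
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j];
  }
  for (int i = 0; i < nr * nc; i++)
    if (out[i] >= EDT_INF) out[i] = R_PosInf;
  return out;
}
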