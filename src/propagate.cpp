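#include <Rcpp.h>
using namespace Rcpp;

// Generation-wise propagation of the additive relationship matrix.
// A (m x m) is the relationship matrix among the previous generation's
// parents; s and d are 0-based rows in A of each new parent's sire and dam.
// For x != y: a(x,y) = 0.25 * (a(sx,sy) + a(sx,dy) + a(dx,sy) + a(dx,dy));
// diagonal: a(x,x) = 1 + 0.5 * a(sx,dx). Identical to the tabular method
// restricted to the new parents when generations are discrete.
//
// Two column-major passes keep the access pattern cache-friendly:
// T(i,c) = A(s_i,c) + A(d_i,c), then out(i,j) = 0.25 * (T(i,s_j) + T(i,d_j)).
// [[Rcpp::export]]
NumericMatrix propagate_A_cpp(const NumericMatrix& A,
                              const IntegerVector& s,
                              const IntegerVector& d) {
  const int n = s.size();
  const int m = A.nrow();
  NumericMatrix out = no_init(n, n);
  std::vector<double> T(static_cast<size_t>(n) * m);
  const double* a = A.begin();
  for (int c = 0; c < m; ++c) {
    const double* col = a + static_cast<size_t>(c) * m;
    double* tcol = T.data() + static_cast<size_t>(c) * n;
    for (int i = 0; i < n; ++i) tcol[i] = col[s[i]] + col[d[i]];
  }
  double* o = out.begin();
  for (int j = 0; j < n; ++j) {
    const double* ts = T.data() + static_cast<size_t>(s[j]) * n;
    const double* td = T.data() + static_cast<size_t>(d[j]) * n;
    double* ocol = o + static_cast<size_t>(j) * n;
    for (int i = 0; i < n; ++i) ocol[i] = 0.25 * (ts[i] + td[i]);
  }
  for (int j = 0; j < n; ++j)
    out(j, j) = 1.0 + 0.5 * A(s[j], d[j]);
  return out;
}
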