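#include <Rcpp.h>
using namespace Rcpp;

// Horn-Schunck fixed-point iteration. The neighborhood average uses the
// classic kernel (1/6 edge, 1/12 diagonal) with replicated boundaries,
// matching the reference R implementation exactly.

static inline double hs_avg_at(const NumericMatrix& m, int i, int j,
                               int n, int p) {
  int iu = i > 0 ? i - 1 : 0, id = i < n - 1 ? i + 1 : n - 1;
  int jl = j > 0 ? j - 1 : 0, jr = j < p - 1 ? j + 1 : p - 1;
  double edge = m(iu, j) + m(id, j) + m(i, jl) + m(i, jr);
  double diag = m(iu, jl) + m(iu, jr) + m(id, jl) + m(id, jr);
  return edge / 6.0 + diag / 12.0;
}

// [[Rcpp::export(name = ".hs_iterate_cpp")]]
List hs_iterate_cpp(NumericMatrix Ix, NumericMatrix Iy, NumericMatrix It,
                    double alpha, int n_iter,
                    NumericMatrix u0, NumericMatrix v0) {
  int n = Ix.nrow(), p = Ix.ncol();
  NumericMatrix u = clone(u0), v = clone(v0);
  NumericMatrix ubar(n, p), vbar(n, p);
  double a2 = alpha * alpha;
  for (int k = 0; k < n_iter; ++k) {
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) {
        ubar(i, j) = hs_avg_at(u, i, j, n, p);
        vbar(i, j) = hs_avg_at(v, i, j, n, p);
      }
    }
    for (int j = 0; j < p; ++j) {
      for (int i = 0; i < n; ++i) {
        double ix = Ix(i, j), iy = Iy(i, j);
        double t = (ix * ubar(i, j) + iy * vbar(i, j) + It(i, j)) /
          (a2 + ix * ix + iy * iy);
        u(i, j) = ubar(i, j) - ix * t;
        v(i, j) = vbar(i, j) - iy * t;
      }
    }
  }
  return List::create(Named("u") = u, Named("v") = v);
}
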