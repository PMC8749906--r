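#include <Rcpp.h>
using namespace Rcpp;

// Online Kohonen training: constant learning rate, bubble neighbourhood
// on a rectangular grid with Chebyshev grid distance, radius schedule
// supplied per epoch.  Presentation orders (0-based) are generated on the
// R side so determinism follows R's RNG.
// [[Rcpp::export(name = ".somTrainCpp")]]
List somTrainCpp(NumericMatrix w0, NumericMatrix X, IntegerMatrix orders,
                 double lr, NumericVector radii,
                 int gridRows, int gridCols) {
  const int nUnits = w0.nrow(), m = w0.ncol();
  const int n = X.nrow(), epochs = orders.ncol();
  NumericMatrix W = clone(w0);
  NumericVector qe(epochs);

  for (int e = 0; e < epochs; ++e) {
    const double radius = radii[e];
    double err = 0.0;
    for (int t = 0; t < n; ++t) {
      const int i = orders(t, e);
      // best-matching unit, ties broken by lowest index
      int bmu = 0;
      double best = R_PosInf;
      for (int u = 0; u < nUnits; ++u) {
        double d2 = 0.0;
        for (int j = 0; j < m; ++j) {
          const double diff = X(i, j) - W(u, j);
          d2 += diff * diff;
        }
        if (d2 < best) { best = d2; bmu = u; }
      }
      err += std::sqrt(best);
      const int br = bmu / gridCols, bc = bmu % gridCols;
      for (int u = 0; u < nUnits; ++u) {
        const int dr = std::abs(u / gridCols - br);
        const int dc = std::abs(u % gridCols - bc);
        const int cheb = dr > dc ? dr : dc;
        if (cheb <= radius)
          for (int j = 0; j < m; ++j)
            W(u, j) += lr * (X(i, j) - W(u, j));
      }
    }
    qe[e] = err / n;
  }
  return List::create(Named("weights") = W, Named("qe") = qe);
}
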