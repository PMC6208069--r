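#include <Rcpp.h>
using namespace Rcpp;

// Nearest destination point for every query point (exhaustive, deterministic;
// ties broken by the lowest destination index). Returns 1-based indices and
// Euclidean distances.
// [[Rcpp::export(name = ".closest_point")]]
List closest_point(NumericMatrix query, NumericMatrix dest) {
  const int n = query.nrow(), m = dest.nrow();
  IntegerVector idx(n);
  NumericVector dist(n);
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = R_PosInf;
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      const double dx = dest(j, 0) - qx;
      const double dy = dest(j, 1) - qy;
      const double dz = dest(j, 2) - qz;
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) { best = d2; bj = j; }
    }
    idx[i] = bj + 1;
    dist[i] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
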