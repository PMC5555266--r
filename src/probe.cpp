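#include <Rcpp.h>
using namespace Rcpp;

// Largest probe-sphere radius at each query point: min over atoms of
// (Euclidean distance to the atom centre) minus the atom's hard-sphere
// radius. Negative values mean the point lies inside an atom.
//
// points: m x 3, coords: n x 3, radii: length n. Both in Angstrom.
// [[Rcpp::export(name = ".probe_radius_points")]]
NumericVector probe_radius_points(NumericMatrix points,
                                  NumericMatrix coords,
                                  NumericVector radii) {
  const int m = points.nrow();
  const int n = coords.nrow();
  if (coords.ncol() != 3 || points.ncol() != 3)
    stop("coordinate matrices must have 3 columns");
  if (radii.size() != n)
    stop("radii length must match atom count");
  NumericVector out(m);
  for (int j = 0; j < m; ++j) {
    const double px = points(j, 0), py = points(j, 1), pz = points(j, 2);
    double best = R_PosInf;
    for (int i = 0; i < n; ++i) {
      const double dx = coords(i, 0) - px;
      const double dy = coords(i, 1) - py;
      const double dz = coords(i, 2) - pz;
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz) - radii[i];
      if (d < best) best = d;
    }
    out[j] = best;
  }
  return out;
}
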