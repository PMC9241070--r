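// Shrake-Rupley solvent-accessible surface area on a deterministic
// golden-spiral point mesh.  Per-atom exposed area of the solvent-expanded
// sphere (radius + probe); neighbours prefiltered by sum of expanded radii.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".sasa_atoms")]]
arma::vec sasa_atoms(arma::mat coords, arma::vec radii, double probe,
                     int n_points) {
  const int n = coords.n_rows;
  if ((int)radii.n_elem != n) Rcpp::stop("radii length mismatch");
  // golden-spiral quasi-uniform unit sphere mesh
  mat pts(n_points, 3);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double y = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - y * y));
    double th = golden * i;
    pts(i, 0) = std::cos(th) * r;
    pts(i, 1) = y;
    pts(i, 2) = std::sin(th) * r;
  }
  vec er = radii + probe;            // expanded radii
  vec area(n, fill::zeros);
  for (int i = 0; i < n; ++i) {
    rowvec ci = coords.row(i);
    // neighbour prefilter
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double lim = er(i) + er(j);
      rowvec d = coords.row(j) - ci;
      if (dot(d, d) < lim * lim) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      rowvec p = ci + er(i) * pts.row(k);
      bool buried = false;
      for (size_t q = 0; q < nb.size(); ++q) {
        int j = nb[q];
        rowvec d = p - coords.row(j);
        if (dot(d, d) < er(j) * er(j)) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    area(i) = 4.0 * M_PI * er(i) * er(i) * exposed / n_points;
  }
  return area;
}
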