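#include <Rcpp.h>
using namespace Rcpp;

// Deterministic quasi-uniform unit-sphere quadrature (Fibonacci spiral).
static std::vector<double> sphere_points(int n) {
  std::vector<double> pts(3 * n);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n; ++i) {
    double z = 1.0 - (2.0 * i + 1.0) / n;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * i;
    pts[3 * i] = r * std::cos(th);
    pts[3 * i + 1] = r * std::sin(th);
    pts[3 * i + 2] = z;
  }
  return pts;
}

//' @noRd
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii,
                       double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  std::vector<double> pts = sphere_points(n_points);
  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xyz(i, 0);
      double dy = xyz(j, 1) - xyz(i, 1);
      double dz = xyz(j, 2) - xyz(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < 1e-12)
        stop("coincident atom centers (atoms %d and %d)", i + 1, j + 1);
      double rr = er[i] + er[j];
      if (d2 < rr * rr) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < n_points; ++p) {
      double px = xyz(i, 0) + er[i] * pts[3 * p];
      double py = xyz(i, 1) + er[i] * pts[3 * p + 1];
      double pz = xyz(i, 2) + er[i] * pts[3 * p + 2];
      bool free_pt = true;
      for (size_t k = 0; k < nbr.size(); ++k) {
        int j = nbr[k];
        double dx = px - xyz(j, 0);
        double dy = py - xyz(j, 1);
        double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < er[j] * er[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * acc / n_points;
  }
  return area;
}

//' @noRd
// [[Rcpp::export(name = ".clash_score_cpp")]]
double clash_score_cpp(NumericMatrix a, NumericVector ra,
                       NumericMatrix b, NumericVector rb) {
  double s = 0.0;
  for (int i = 0; i < a.nrow(); ++i) {
    for (int j = 0; j < b.nrow(); ++j) {
      double dx = a(i, 0) - b(j, 0);
      double dy = a(i, 1) - b(j, 1);
      double dz = a(i, 2) - b(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ov = ra[i] + rb[j] - d;
      if (ov > 0.0) s += ov * ov;
    }
  }
  return s;
}
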