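#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Exact Euclidean distance transform of a 3D binary mask, separable
// lower-envelope-of-parabolas algorithm (Felzenszwalb & Huttenlocher),
// generalised to anisotropic voxel spacing. Returns, for each foreground
// voxel, the distance (physical units) to the nearest background voxel;
// background voxels get 0. Voxels outside the array are background.

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double qs = q * s;
    double sI;
    while (true) {
      double ps = v[k] * s;
      sI = ((f[q] + qs * qs) - (f[v[k]] + ps * ps)) / (2 * qs - 2 * ps);
      if (sI > z[k]) break;
      --k;
    }
    ++k;
    v[k] = q;
    z[k] = sI;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qs = q * s;
    while (z[k + 1] < qs) ++k;
    double ps = v[k] * s;
    d[q] = (qs - ps) * (qs - ps) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(NumericVector mask, NumericVector spacing) {
  IntegerVector md = mask.attr("dim");
  const int D = md[0], H = md[1], W = md[2];
  const double INF = 1e30;
  NumericVector out(D * H * W);

  // Distances are measured to in-array background voxels (voxels beyond
  // the array border are not treated as background), matching the usual
  // EDT convention.
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      for (int d = 0; d < D; ++d) {
        int i = d + D * (h + H * w);
        out[i] = mask[i] > 0 ? INF : 0.0;
      }

  std::vector<double> f, dcol;
  // axis 1 (d), spacing[0]
  f.resize(D); dcol.resize(D);
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) f[d] = out[d + D * (h + H * w)];
      dt1d(f, dcol, spacing[0]);
      for (int d = 0; d < D; ++d) out[d + D * (h + H * w)] = dcol[d];
    }
  // axis 2 (h), spacing[1]
  f.resize(H); dcol.resize(H);
  for (int w = 0; w < W; ++w)
    for (int d = 0; d < D; ++d) {
      for (int h = 0; h < H; ++h) f[h] = out[d + D * (h + H * w)];
      dt1d(f, dcol, spacing[1]);
      for (int h = 0; h < H; ++h) out[d + D * (h + H * w)] = dcol[h];
    }
  // axis 3 (w), spacing[2]
  f.resize(W); dcol.resize(W);
  for (int h = 0; h < H; ++h)
    for (int d = 0; d < D; ++d) {
      for (int w = 0; w < W; ++w) f[w] = out[d + D * (h + H * w)];
      dt1d(f, dcol, spacing[2]);
      for (int w = 0; w < W; ++w) out[d + D * (h + H * w)] = dcol[w];
    }

  for (int i = 0; i < D * H * W; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = IntegerVector::create(D, H, W);
  return out;
}
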