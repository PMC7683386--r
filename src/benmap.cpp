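#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Template-pair match counts for Sample Entropy.
// Templates of length m start at positions 0..T-m-1 (Richman-Moorman
// convention: the same T-m starting positions at both lengths, so the
// length-(m+1) pair set is a subset of the length-m pair set and A <= B).
// Match predicate: Chebyshev distance <= r (strict=true uses < r).
static void sampen_counts(const double* x, int T, int m, double r,
                          bool strict, double& B, double& A) {
  const int N = T - m;
  B = 0.0;
  A = 0.0;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double d = 0.0;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        double ad = std::fabs(x[i + k] - x[j + k]);
        if (ad > d) d = ad;
        if (strict ? (d >= r) : (d > r)) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      double dm = std::fabs(x[i + m] - x[j + m]);
      if (dm < d) dm = d;
      if (strict ? (dm < r) : (dm <= r)) A += 1.0;
    }
  }
}

// [[Rcpp::export]]
List cpp_match_counts(NumericVector x, int m, double r_abs, bool strict) {
  double B, A;
  sampen_counts(x.begin(), x.size(), m, r_abs, strict, B, A);
  return List::create(_["B"] = B, _["A"] = A);
}

// [[Rcpp::export]]
double cpp_sample_entropy(NumericVector x, int m, double r, bool sd_relative,
                          bool strict) {
  const int T = x.size();
  double r_abs = r;
  if (sd_relative) {
    double mu = 0.0;
    for (int t = 0; t < T; ++t) mu += x[t];
    mu /= T;
    double ss = 0.0;
    for (int t = 0; t < T; ++t) ss += (x[t] - mu) * (x[t] - mu);
    // sample SD (n-1), the MATLAB std() convention of the toolbox lineage
    double sd = std::sqrt(ss / (T - 1));
    if (sd <= 0.0) return NA_REAL;
    r_abs = r * sd;
  }
  double B, A;
  sampen_counts(x.begin(), T, m, r_abs, strict, B, A);
  if (B <= 0.0 || A <= 0.0) return NA_REAL;
  return std::log(B / A);
}

// Voxelwise Sample Entropy over a 4D image (x,y,z,t in R array order).
// [[Rcpp::export]]
NumericVector cpp_ben_map(NumericVector img, IntegerVector dim,
                          LogicalVector mask, int m, double r,
                          bool sd_relative, bool strict) {
  const int nx = dim[0], ny = dim[1], nz = dim[2], T = dim[3];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  NumericVector out(nvox, NA_REAL);
  std::vector<double> series(T);
  for (R_xlen_t v = 0; v < nvox; ++v) {
    if (!mask[v]) continue;
    for (int t = 0; t < T; ++t) series[t] = img[v + nvox * t];
    NumericVector s(series.begin(), series.end());
    out[v] = cpp_sample_entropy(s, m, r, sd_relative, strict);
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Connected-component labeling of a 3D boolean lattice.
// connectivity: 6 (faces), 18 (faces+edges), 26 (faces+edges+corners).
// Labels are assigned in scan order (x fastest), so they are deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector binary, IntegerVector dim,
                                 int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;
  // neighbor offsets
  std::vector<int> dxs, dys, dzs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if ((connectivity == 6 && ord > 1) || (connectivity == 18 && ord > 2))
          continue;
        dxs.push_back(dx); dys.push_back(dy); dzs.push_back(dz);
      }
  IntegerVector labels(nvox, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;
  for (R_xlen_t s = 0; s < nvox; ++s) {
    if (!binary[s] || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / ((R_xlen_t)nx * ny);
      for (size_t q = 0; q < dxs.size(); ++q) {
        int xx = x + dxs[q], yy = y + dys[q], zz = z + dzs[q];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t w = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (binary[w] && labels[w] == 0) {
          labels[w] = next_label;
          stack.push_back(w);
        }
      }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

static inline int reflect_index(int i, int n) {
  // symmetric reflection: ... c b a | a b c ... (unit-mass kernels then
  // preserve constants exactly)
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

static void smooth_axis(std::vector<double>& data, int nx, int ny, int nz,
                        int axis, double sigma) {
  if (sigma <= 0.0) return;
  int rad = (int)std::ceil(4.0 * sigma);
  std::vector<double> w(2 * rad + 1);
  double sum = 0.0;
  for (int k = -rad; k <= rad; ++k) {
    w[k + rad] = std::exp(-0.5 * k * k / (sigma * sigma));
    sum += w[k + rad];
  }
  for (double& wk : w) wk /= sum;
  int n[3] = {nx, ny, nz};
  R_xlen_t stride[3] = {1, nx, (R_xlen_t)nx * ny};
  int na = n[axis];
  R_xlen_t sa = stride[axis];
  int nb = n[(axis + 1) % 3], nc = n[(axis + 2) % 3];
  R_xlen_t sb = stride[(axis + 1) % 3], sc = stride[(axis + 2) % 3];
  std::vector<double> line(na);
  for (int b = 0; b < nb; ++b)
    for (int c = 0; c < nc; ++c) {
      R_xlen_t base = b * sb + c * sc;
      for (int a = 0; a < na; ++a) line[a] = data[base + a * sa];
      for (int a = 0; a < na; ++a) {
        double acc = 0.0;
        for (int k = -rad; k <= rad; ++k)
          acc += w[k + rad] * line[reflect_index(a + k, na)];
        data[base + a * sa] = acc;
      }
    }
}

// Separable Gaussian smoothing of a 3D volume (sigma per axis, voxel units),
// reflective boundary.
// [[Rcpp::export]]
NumericVector cpp_smooth3d(NumericVector vol, IntegerVector dim,
                           NumericVector sigma_vox) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> data(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis)
    smooth_axis(data, nx, ny, nz, axis, sigma_vox[axis]);
  NumericVector out(data.begin(), data.end());
  out.attr("dim") = dim;
  return out;
}
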