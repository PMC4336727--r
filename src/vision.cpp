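// Low-level vision kernels: dense multi-scale SIFT, Lloyd k-means,
// nearest-center assignment, bilinear resize.
//
// Conventions shared with the R layer:
//  * luminance matrices are H x W (row = y, col = x), values in [0, 255];
//  * pixel coordinates are 0-based; out-of-image support contributes zero
//    gradient;
//  * gradients by central differences with zero padding beyond the border;
//  * angles in [0, 2*pi), measured with y pointing down (atan2(gy, gx));
//  * gradient orientation is discretized once per pixel to FINE = 288
//    levels (1.25 deg), an exact common refinement of the 36-bin
//    orientation histogram and the 8 descriptor bins, so dense and
//    single-point paths bin identically.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
#include <cfloat>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;
static const int FINE = 288; // lcm(36, 8) * 1 -> 36 * 8

struct GradientField {
  int H, W;
  std::vector<float> mag;     // H*W column-major, 0 outside
  std::vector<uint16_t> fine; // orientation in FINE levels
  inline bool inside(int x, int y) const {
    return x >= 0 && y >= 0 && x < W && y < H;
  }
  inline float m(int x, int y) const {
    return inside(x, y) ? mag[(size_t)x * H + y] : 0.0f;
  }
  inline int f(int x, int y) const {
    return inside(x, y) ? fine[(size_t)x * H + y] : 0;
  }
};

static GradientField gradient_field(const NumericMatrix& lum) {
  GradientField g;
  g.H = lum.nrow();
  g.W = lum.ncol();
  g.mag.assign((size_t)g.H * g.W, 0.0f);
  g.fine.assign((size_t)g.H * g.W, 0);
  const double* L = &lum(0, 0);
  const int H = g.H, W = g.W;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double xr = (x + 1 < W) ? L[(size_t)(x + 1) * H + y] : 0.0;
      const double xl = (x - 1 >= 0) ? L[(size_t)(x - 1) * H + y] : 0.0;
      const double yd = (y + 1 < H) ? L[(size_t)x * H + y + 1] : 0.0;
      const double yu = (y - 1 >= 0) ? L[(size_t)x * H + y - 1] : 0.0;
      const double gx = 0.5 * (xr - xl);
      const double gy = 0.5 * (yd - yu);
      const double m = std::sqrt(gx * gx + gy * gy);
      if (m <= 0.0) continue;
      double a = std::atan2(gy, gx);
      if (a < 0.0) a += TWO_PI;
      int f = (int)std::floor(a * FINE / TWO_PI);
      if (f >= FINE) f = FINE - 1;
      if (f < 0) f = 0;
      g.mag[(size_t)x * H + y] = (float)m;
      g.fine[(size_t)x * H + y] = (uint16_t)f;
    }
  }
  return g;
}

// Gaussian weight table over the circular support of one radius
// (sigma = radius / 2); entries outside the circle are 0.
static std::vector<float> gauss_table(int radius) {
  const int side = 2 * radius + 1;
  std::vector<float> w((size_t)side * side, 0.0f);
  const double sigma = radius / 2.0;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double r2 = (double)radius * radius;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx) {
      const double d2 = (double)dx * dx + (double)dy * dy;
      if (d2 <= r2)
        w[(size_t)(dy + radius) * side + (dx + radius)] =
            (float)std::exp(-d2 * inv2s2);
    }
  return w;
}

// Peak of the 36-bin weighted orientation histogram; lowest bin on ties;
// returns the bin index (angle = bin * 2*pi/36), or -1 for zero support.
static int dominant_bin(const GradientField& g, int cx, int cy, int radius,
                        const std::vector<float>& wtab) {
  float hist[36] = {0};
  const int side = 2 * radius + 1;
  for (int dy = -radius; dy <= radius; ++dy) {
    const int y = cy + dy;
    for (int dx = -radius; dx <= radius; ++dx) {
      const float w = wtab[(size_t)(dy + radius) * side + (dx + radius)];
      if (w <= 0.0f) continue;
      const float m = g.m(cx + dx, y);
      if (m <= 0.0f) continue;
      hist[g.f(cx + dx, y) / 8] += m * w;
    }
  }
  int best = 0;
  float bv = hist[0];
  for (int i = 1; i < 36; ++i)
    if (hist[i] > bv) { bv = hist[i]; best = i; }
  return (bv > 0.0f) ? best : -1;
}

// 4x4 spatial patches x 8 orientation bins, hard assignment, square of
// side 4*radius rotated by theta; nearest-pixel sampling via incremental
// rotated stepping. L2 normalize, clip at 0.2, renormalize; zero-gradient
// support -> zero vector. theta_units = theta / (2*pi/FINE).
static void sift_descriptor_field(const GradientField& g, int cx, int cy,
                                  int radius, double theta,
                                  double* out /* 128 */) {
  float acc[128] = {0};
  const float ct = (float)std::cos(theta), st = (float)std::sin(theta);
  const int half = 2 * radius;
  int tu = (int)std::lround(theta * FINE / TWO_PI) % FINE;
  if (tu < 0) tu += FINE;
  // fast path: every sample is guaranteed in-bounds
  const int reach = (int)std::ceil(2.8285 * radius) + 1;
  const bool interior = (cx - reach >= 0 && cx + reach < g.W &&
                         cy - reach >= 0 && cy + reach < g.H);
  for (int v = -half; v < half; ++v) {
    const int prow4 = ((v + half) / radius) * 4;
    // row start in image coords
    float fx = cx + (-half) * ct - v * st;
    float fy = cy + (-half) * st + v * ct;
    for (int u = -half; u < half; ++u, fx += ct, fy += st) {
      const int px = (int)lrintf(fx);
      const int py = (int)lrintf(fy);
      float m;
      int f;
      if (interior) {
        m = g.mag[(size_t)px * g.H + py];
        if (m <= 0.0f) continue;
        f = g.fine[(size_t)px * g.H + py];
      } else {
        m = g.m(px, py);
        if (m <= 0.0f) continue;
        f = g.f(px, py);
      }
      int rb = f - tu;
      if (rb < 0) rb += FINE;
      const int pcol = (u + half) / radius;
      acc[(prow4 + pcol) * 8 + rb / 36] += m;
    }
  }
  double n2 = 0.0;
  for (int i = 0; i < 128; ++i) n2 += (double)acc[i] * acc[i];
  if (n2 <= 0.0) {
    for (int i = 0; i < 128; ++i) out[i] = 0.0;
    return;
  }
  double inv = 1.0 / std::sqrt(n2);
  n2 = 0.0;
  for (int i = 0; i < 128; ++i) {
    double v = acc[i] * inv;
    if (v > 0.2) v = 0.2;
    out[i] = v;
    n2 += v * v;
  }
  inv = 1.0 / std::sqrt(n2);
  for (int i = 0; i < 128; ++i) out[i] *= inv;
}

// [[Rcpp::export(name = ".dominant_orientation_cpp")]]
double dominant_orientation_cpp(NumericMatrix lum, int cx, int cy, int radius) {
  GradientField g = gradient_field(lum);
  std::vector<float> wtab = gauss_table(radius);
  const int b = dominant_bin(g, cx, cy, radius, wtab);
  return (b < 0) ? 0.0 : b * (TWO_PI / 36);
}

// [[Rcpp::export(name = ".sift_descriptor_cpp")]]
NumericVector sift_descriptor_cpp(NumericMatrix lum, int cx, int cy,
                                  int radius, double orientation) {
  GradientField g = gradient_field(lum);
  NumericVector out(128);
  sift_descriptor_field(g, cx, cy, radius, orientation, &out[0]);
  return out;
}

// Dense multi-scale extraction: rows ordered point-major, radius-minor
// (row = p * n_radii + r_index); each point re-oriented per scale.
// [[Rcpp::export(name = ".dense_sift_cpp")]]
List dense_sift_cpp(NumericMatrix lum, IntegerVector xs, IntegerVector ys,
                    IntegerVector radii) {
  const int np = xs.size(), nr = radii.size();
  GradientField g = gradient_field(lum);
  std::vector<std::vector<float>> wtabs(nr);
  for (int r = 0; r < nr; ++r) wtabs[r] = gauss_table(radii[r]);
  NumericMatrix desc(np * nr, 128);
  NumericVector ori(np * nr);
  std::vector<double> buf(128);
  for (int p = 0; p < np; ++p) {
    for (int r = 0; r < nr; ++r) {
      const int b = dominant_bin(g, xs[p], ys[p], radii[r], wtabs[r]);
      const double th = (b < 0) ? 0.0 : b * (TWO_PI / 36);
      sift_descriptor_field(g, xs[p], ys[p], radii[r], th, buf.data());
      const int row = p * nr + r;
      ori[row] = th;
      for (int i = 0; i < 128; ++i) desc(row, i) = buf[i];
    }
  }
  return List::create(_["descriptors"] = desc, _["orientations"] = ori);
}

// Nearest center by Euclidean distance, ties -> lowest index. Centers are
// transposed to d x k float rows so each nonzero descriptor dimension is a
// contiguous SIMD axpy over all k centers; argmin of ||c||^2 - 2 x.c. The
// float rounding (~1e-6 relative) cannot flip an argmin for non-tied
// inputs; exact input ties stay exact ties in float.
// [[Rcpp::export(name = ".assign_words_cpp")]]
IntegerVector assign_words_cpp(NumericMatrix X, NumericMatrix C) {
  const int n = X.nrow(), d = X.ncol(), k = C.nrow();
  if (C.ncol() != d) stop("descriptor/codebook dimension mismatch");
  std::vector<float> Ct((size_t)d * k); // row t holds center coords of dim t
  std::vector<float> cn(k, 0.0f);
  for (int j = 0; j < k; ++j) {
    float s = 0.0f;
    for (int t = 0; t < d; ++t) {
      const float v = (float)C(j, t);
      Ct[(size_t)t * k + j] = v;
      s += v * v;
    }
    cn[j] = s;
  }
  std::vector<float> acc(k);
  std::vector<float> xrow(d);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < d; ++t) xrow[t] = (float)X(i, t);
    std::fill(acc.begin(), acc.end(), 0.0f);
    for (int t = 0; t < d; ++t) {
      const float xv = xrow[t];
      if (xv == 0.0f) continue;
      const float* crow = &Ct[(size_t)t * k];
      for (int j = 0; j < k; ++j) acc[j] += xv * crow[j];
    }
    float best = FLT_MAX;
    int bj = 0;
    for (int j = 0; j < k; ++j) {
      const float dist = cn[j] - 2.0f * acc[j];
      if (dist < best) { best = dist; bj = j; }
    }
    out[i] = bj + 1; // 1-based
  }
  return out;
}

// Lloyd's algorithm from given initial centers (rows of X, 1-based
// init_idx). Stops when assignments are unchanged or after max_iter.
// Empty clusters keep their previous center. Distance scan in float via
// the same transposed-axpy layout; center updates and the final inertia
// in double.
// [[Rcpp::export(name = ".kmeans_lloyd_cpp")]]
List kmeans_lloyd_cpp(NumericMatrix X, IntegerVector init_idx, int max_iter) {
  const int n = X.nrow(), d = X.ncol(), k = init_idx.size();
  std::vector<double> C((size_t)k * d); // row-major centers
  for (int j = 0; j < k; ++j) {
    const int src = init_idx[j] - 1;
    for (int t = 0; t < d; ++t) C[(size_t)j * d + t] = X(src, t);
  }
  std::vector<float> Xf((size_t)n * d); // row-major float copy
  std::vector<double> Xd((size_t)n * d);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < d; ++t) {
      Xd[(size_t)i * d + t] = X(i, t);
      Xf[(size_t)i * d + t] = (float)X(i, t);
    }

  std::vector<int> assign(n, -1), count(k);
  std::vector<float> Ct((size_t)d * k), cn(k), acc(k);
  std::vector<double> sums((size_t)k * d);
  int iter = 0;
  bool converged = false;
  while (iter < max_iter) {
    ++iter;
    for (int j = 0; j < k; ++j) {
      double s = 0.0;
      for (int t = 0; t < d; ++t) {
        const double v = C[(size_t)j * d + t];
        Ct[(size_t)t * k + j] = (float)v;
        s += v * v;
      }
      cn[j] = (float)s;
    }
    bool changed = false;
    for (int i = 0; i < n; ++i) {
      const float* x = &Xf[(size_t)i * d];
      std::fill(acc.begin(), acc.end(), 0.0f);
      for (int t = 0; t < d; ++t) {
        const float xv = x[t];
        if (xv == 0.0f) continue;
        const float* crow = &Ct[(size_t)t * k];
        for (int j = 0; j < k; ++j) acc[j] += xv * crow[j];
      }
      float best = FLT_MAX;
      int bj = 0;
      for (int j = 0; j < k; ++j) {
        const float dist = cn[j] - 2.0f * acc[j];
        if (dist < best) { best = dist; bj = j; }
      }
      if (assign[i] != bj) changed = true;
      assign[i] = bj;
    }
    if (!changed) { converged = true; break; }
    std::fill(sums.begin(), sums.end(), 0.0);
    std::fill(count.begin(), count.end(), 0);
    for (int i = 0; i < n; ++i) {
      const int j = assign[i];
      ++count[j];
      const double* x = &Xd[(size_t)i * d];
      double* s = &sums[(size_t)j * d];
      for (int t = 0; t < d; ++t) s[t] += x[t];
    }
    for (int j = 0; j < k; ++j) {
      if (count[j] == 0) continue; // keep previous center
      const double inv = 1.0 / count[j];
      for (int t = 0; t < d; ++t)
        C[(size_t)j * d + t] = sums[(size_t)j * d + t] * inv;
    }
  }

  double inertia = 0.0;
  for (int i = 0; i < n; ++i) {
    const double* x = &Xd[(size_t)i * d];
    const double* c = &C[(size_t)assign[i] * d];
    double s = 0.0;
    for (int t = 0; t < d; ++t) {
      const double diff = x[t] - c[t];
      s += diff * diff;
    }
    inertia += s;
  }
  NumericMatrix centers(k, d);
  for (int j = 0; j < k; ++j)
    for (int t = 0; t < d; ++t) centers(j, t) = C[(size_t)j * d + t];
  IntegerVector cl(n);
  for (int i = 0; i < n; ++i) cl[i] = assign[i] + 1;
  return List::create(_["centers"] = centers, _["cluster"] = cl,
                      _["inertia"] = inertia, _["iterations"] = iter,
                      _["converged"] = converged);
}

// Bilinear resize of one plane to out_h x out_w; border clamped.
// [[Rcpp::export(name = ".resize_bilinear_cpp")]]
NumericMatrix resize_bilinear_cpp(NumericMatrix src, int out_h, int out_w) {
  const int H = src.nrow(), W = src.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int x = 0; x < out_w; ++x) {
    double fx = (x + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0;
    if (fx > W - 1) fx = W - 1;
    const int x0 = (int)std::floor(fx);
    const int x1 = (x0 + 1 < W) ? x0 + 1 : x0;
    const double wx = fx - x0;
    for (int y = 0; y < out_h; ++y) {
      double fy = (y + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0;
      if (fy > H - 1) fy = H - 1;
      const int y0 = (int)std::floor(fy);
      const int y1 = (y0 + 1 < H) ? y0 + 1 : y0;
      const double wy = fy - y0;
      const double top = src(y0, x0) * (1 - wx) + src(y0, x1) * wx;
      const double bot = src(y1, x0) * (1 - wx) + src(y1, x1) * wx;
      out(y, x) = top * (1 - wy) + bot * wy;
    }
  }
  return out;
}
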