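#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

// Images are R matrices / arrays indexed [row, col(, channel)] with
// row = y + 1, col = x + 1 in the package's 0-based pixel coordinates.
// Pixel centers sit at integer coordinates.

// ---------------------------------------------------------------------------
// Separable Gaussian blur, replicate border.
// ---------------------------------------------------------------------------

static std::vector<double> gaussian_kernel(int ksize, double sigma) {
  std::vector<double> k(ksize);
  int half = ksize / 2;
  double sum = 0.0;
  for (int i = 0; i < ksize; ++i) {
    double d = i - half;
    k[i] = std::exp(-0.5 * d * d / (sigma * sigma));
    sum += k[i];
  }
  for (int i = 0; i < ksize; ++i) k[i] /= sum;
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, int ksize, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (ksize <= 1) return clone(img);
  std::vector<double> k = gaussian_kernel(ksize, sigma);
  int half = ksize / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // horizontal pass
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double acc = 0.0;
      for (int i = -half; i <= half; ++i) {
        int xx = std::min(std::max(x + i, 0), w - 1);
        acc += k[i + half] * img(y, xx);
      }
      tmp(y, x) = acc;
    }
  }
  // vertical pass
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int i = -half; i <= half; ++i) {
        int yy = std::min(std::max(y + i, 0), h - 1);
        acc += k[i + half] * tmp(yy, x);
      }
      out(y, x) = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Iterated box blur (running sums, replicate border): three passes
// approximate a Gaussian with sigma^2 = iters * ((2r+1)^2 - 1) / 12 at O(1)
// cost per pixel. Used for structure-tensor integration where the exact
// kernel shape is irrelevant.
// ---------------------------------------------------------------------------

static void box_pass_cols(std::vector<double>& v, int h, int w, int r) {
  std::vector<double> col(h);
  double norm = 1.0 / (2 * r + 1);
  for (int x = 0; x < w; ++x) {
    double* c = v.data() + (size_t)x * h;
    double acc = (r + 1) * c[0];
    for (int y = 0; y < r; ++y) acc += c[std::min(y, h - 1)];
    for (int y = 0; y < h; ++y) {
      acc += c[std::min(y + r, h - 1)] - c[std::max(y - r - 1, 0)];
      col[y] = acc * norm;
    }
    std::copy(col.begin(), col.end(), c);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_box_blur(NumericMatrix img, int radius, int iters) {
  int h = img.nrow(), w = img.ncol();
  if (radius < 1) return clone(img);
  std::vector<double> v(img.begin(), img.end());      // column-major
  std::vector<double> vt((size_t)h * w);
  for (int it = 0; it < iters; ++it) {
    box_pass_cols(v, h, w, radius);                   // vertical
    // transpose, blur columns (= horizontal), transpose back
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y)
        vt[(size_t)y * w + x] = v[(size_t)x * h + y];
    box_pass_cols(vt, w, h, radius);
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y)
        v[(size_t)x * h + y] = vt[(size_t)y * w + x];
  }
  NumericMatrix out(h, w);
  std::copy(v.begin(), v.end(), out.begin());
  return out;
}

// ---------------------------------------------------------------------------
// Bilinear resize (align pixel areas: src coord = (dst + 0.5) * scale - 0.5).
// ---------------------------------------------------------------------------

static inline double sample_bilinear_clamped(const NumericMatrix& img,
                                             double x, double y) {
  int h = img.nrow(), w = img.ncol();
  if (x < 0) x = 0; if (x > w - 1) x = w - 1;
  if (y < 0) y = 0; if (y > h - 1) y = h - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(NumericMatrix img, int out_h, int out_w) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix out(out_h, out_w);
  double sx = (double)w / out_w, sy = (double)h / out_h;
  for (int y = 0; y < out_h; ++y) {
    double ys = (y + 0.5) * sy - 0.5;
    for (int x = 0; x < out_w; ++x) {
      double xs = (x + 0.5) * sx - 0.5;
      out(y, x) = sample_bilinear_clamped(img, xs, ys);
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Projective warp onto a canvas. hinv maps canvas (x, y) -> source (x, y).
// Returns warped channels plus a validity mask (1 where the source covers
// the canvas pixel).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_warp_bilinear(NumericVector img, NumericMatrix hinv,
                       int out_h, int out_w) {
  IntegerVector dims = img.attr("dim");
  int h = dims[0], w = dims[1];
  int nc = (dims.size() == 3) ? dims[2] : 1;
  NumericVector out(out_h * out_w * nc);
  out.attr("dim") = (nc > 1) ? IntegerVector::create(out_h, out_w, nc)
                             : IntegerVector::create(out_h, out_w);
  IntegerMatrix mask(out_h, out_w);
  const double* src = img.begin();
  double* dst = out.begin();
  for (int y = 0; y < out_h; ++y) {
    for (int x = 0; x < out_w; ++x) {
      double d = hinv(2, 0) * x + hinv(2, 1) * y + hinv(2, 2);
      if (std::fabs(d) < 1e-12) continue;
      double xs = (hinv(0, 0) * x + hinv(0, 1) * y + hinv(0, 2)) / d;
      double ys = (hinv(1, 0) * x + hinv(1, 1) * y + hinv(1, 2)) / d;
      if (xs < 0 || xs > w - 1 || ys < 0 || ys > h - 1) continue;
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      int x1 = std::min(x0 + 1, w - 1), y1 = std::min(y0 + 1, h - 1);
      double fx = xs - x0, fy = ys - y0;
      for (int c = 0; c < nc; ++c) {
        const double* p = src + (size_t)c * h * w;
        double v = (1 - fy) * ((1 - fx) * p[x0 * h + y0] + fx * p[x1 * h + y0]) +
                   fy * ((1 - fx) * p[x0 * h + y1] + fx * p[x1 * h + y1]);
        dst[(size_t)c * out_h * out_w + (size_t)x * out_h + y] = v;
      }
      mask(y, x) = 1;
    }
  }
  return List::create(_["pixels"] = out, _["mask"] = mask);
}

// ---------------------------------------------------------------------------
// Circle Hough Transform on a binary edge image.
// Each edge pixel votes for centers lying at distance r; candidate score is
// the supported fraction of the circle perimeter. Candidates are 3x3 local
// maxima of the per-radius accumulator.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_hough_circle(IntegerMatrix edges, NumericVector radii,
                               double score_threshold) {
  int h = edges.nrow(), w = edges.ncol();
  std::vector<int> ex, ey;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (edges(y, x) != 0) { ex.push_back(x); ey.push_back(y); }
  std::vector<double> cand;  // cx, cy, r, score
  if (ex.empty())
    return NumericMatrix(0, 4);
  std::vector<int> acc((size_t)h * w);
  for (int ri = 0; ri < radii.size(); ++ri) {
    double r = radii[ri];
    int ntheta = std::max(64, (int)std::ceil(2.0 * M_PI * r * 1.5));
    std::fill(acc.begin(), acc.end(), 0);
    // cap the per-cell vote of a single edge pixel at 1 by deduplicating
    // consecutive rounded positions along the circle
    for (size_t e = 0; e < ex.size(); ++e) {
      int px = -1, py = -1;
      for (int t = 0; t < ntheta; ++t) {
        double th = 2.0 * M_PI * t / ntheta;
        int cx = (int)std::lround(ex[e] - r * std::cos(th));
        int cy = (int)std::lround(ey[e] - r * std::sin(th));
        if (cx == px && cy == py) continue;
        px = cx; py = cy;
        if (cx >= 0 && cx < w && cy >= 0 && cy < h)
          acc[(size_t)cx * h + cy] += 1;
      }
    }
    double norm = 2.0 * M_PI * r;  // ideal number of supporting edge pixels
    for (int x = 1; x < w - 1; ++x) {
      for (int y = 1; y < h - 1; ++y) {
        int v = acc[(size_t)x * h + y];
        double score = v / norm;
        if (score < score_threshold) continue;
        bool ismax = true;
        for (int dx = -1; dx <= 1 && ismax; ++dx)
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            if (acc[(size_t)(x + dx) * h + (y + dy)] > v) { ismax = false; break; }
          }
        if (ismax) {
          cand.push_back(x); cand.push_back(y);
          cand.push_back(r); cand.push_back(score);
        }
      }
    }
  }
  NumericMatrix out(cand.size() / 4, 4);
  for (int i = 0; i < out.nrow(); ++i)
    for (int j = 0; j < 4; ++j) out(i, j) = cand[(size_t)i * 4 + j];
  return out;
}

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher).
// Input: binary matrix, 1 = feature. Output: distance in pixels to the
// nearest feature pixel (Inf if none).
// ---------------------------------------------------------------------------

static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_edt(IntegerMatrix feature) {
  int h = feature.nrow(), w = feature.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  const double BIG = 1e12;  // finite sentinel: keeps the envelope stable
  NumericMatrix sq(h, w);
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      sq(y, x) = feature(y, x) != 0 ? 0.0 : BIG;
  std::vector<double> f(std::max(h, w)), d(std::max(h, w));
  for (int x = 0; x < w; ++x) {                    // columns
    for (int y = 0; y < h; ++y) f[y] = sq(y, x);
    edt_1d(f, d, h);
    for (int y = 0; y < h; ++y) sq(y, x) = d[y];
  }
  for (int y = 0; y < h; ++y) {                    // rows
    for (int x = 0; x < w; ++x) f[x] = sq(y, x);
    edt_1d(f, d, w);
    for (int x = 0; x < w; ++x) sq(y, x) = d[x];
  }
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      sq(y, x) = (sq(y, x) >= 0.5 * BIG) ? INF : std::sqrt(sq(y, x));
  return sq;
}

// ---------------------------------------------------------------------------
// 3x3 local maxima of a response map with quadratic sub-pixel refinement.
// Returns (x, y, value) rows in 0-based pixel coordinates.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix cpp_local_maxima(NumericMatrix resp, double threshold,
                               int border) {
  int h = resp.nrow(), w = resp.ncol();
  std::vector<double> out;
  for (int x = std::max(border, 1); x < w - std::max(border, 1); ++x) {
    for (int y = std::max(border, 1); y < h - std::max(border, 1); ++y) {
      double v = resp(y, x);
      if (v < threshold) continue;
      bool ismax = true;
      for (int dx = -1; dx <= 1 && ismax; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dx == 0 && dy == 0) continue;
          if (resp(y + dy, x + dx) > v) { ismax = false; break; }
        }
      if (!ismax) continue;
      // quadratic fit: offset = -H^{-1} g
      double gx = 0.5 * (resp(y, x + 1) - resp(y, x - 1));
      double gy = 0.5 * (resp(y + 1, x) - resp(y - 1, x));
      double hxx = resp(y, x + 1) - 2 * v + resp(y, x - 1);
      double hyy = resp(y + 1, x) - 2 * v + resp(y - 1, x);
      double hxy = 0.25 * (resp(y + 1, x + 1) - resp(y + 1, x - 1) -
                           resp(y - 1, x + 1) + resp(y - 1, x - 1));
      double det = hxx * hyy - hxy * hxy;
      double ox = 0.0, oy = 0.0;
      if (std::fabs(det) > 1e-12) {
        ox = -(hyy * gx - hxy * gy) / det;
        oy = -(hxx * gy - hxy * gx) / det;
        if (std::fabs(ox) > 1.0) ox = 0.0;
        if (std::fabs(oy) > 1.0) oy = 0.0;
      }
      out.push_back(x + ox);
      out.push_back(y + oy);
      out.push_back(v);
    }
  }
  NumericMatrix m(out.size() / 3, 3);
  for (int i = 0; i < m.nrow(); ++i)
    for (int j = 0; j < 3; ++j) m(i, j) = out[(size_t)i * 3 + j];
  return m;
}

// ---------------------------------------------------------------------------
// SIFT-style 4x4x8 gradient-histogram descriptors with dominant-orientation
// assignment. Input keypoints: rows (x, y, scale). Output: 128-col descriptor
// matrix (L2-normalized, clipped at 0.2, renormalized — the classical SIFT
// recipe; root-SIFT post-processing happens in R) plus orientations.
// ---------------------------------------------------------------------------

static inline void grad_at(const NumericMatrix& img, double x, double y,
                           double& gx, double& gy) {
  gx = 0.5 * (sample_bilinear_clamped(img, x + 1, y) -
              sample_bilinear_clamped(img, x - 1, y));
  gy = 0.5 * (sample_bilinear_clamped(img, x, y + 1) -
              sample_bilinear_clamped(img, x, y - 1));
}

// [[Rcpp::export]]
List cpp_describe_keypoints(NumericMatrix img, NumericMatrix kps) {
  int n = kps.nrow();
  int h = img.nrow(), w = img.ncol();
  NumericMatrix desc(n, 128);
  NumericVector ori(n);
  LogicalVector keep(n);
  for (int i = 0; i < n; ++i) {
    double kx = kps(i, 0), ky = kps(i, 1), ks = kps(i, 2);
    // --- dominant orientation: 36-bin weighted gradient histogram ---
    int orad = (int)std::ceil(4.0 * ks);
    double osig = 2.0 * ks;
    double hist[36] = {0};
    for (int dy = -orad; dy <= orad; ++dy) {
      for (int dx = -orad; dx <= orad; ++dx) {
        double px = kx + dx, py = ky + dy;
        if (px < 1 || px > w - 2 || py < 1 || py > h - 2) continue;
        double gx, gy;
        grad_at(img, px, py, gx, gy);
        double mag = std::sqrt(gx * gx + gy * gy);
        if (mag <= 0) continue;
        double wgt = std::exp(-0.5 * (dx * dx + dy * dy) / (osig * osig));
        double ang = std::atan2(gy, gx);  // (-pi, pi]
        int bin = (int)std::floor((ang + M_PI) / (2.0 * M_PI) * 36.0);
        if (bin >= 36) bin = 35;
        if (bin < 0) bin = 0;
        hist[bin] += wgt * mag;
      }
    }
    int best = 0;
    for (int b = 1; b < 36; ++b) if (hist[b] > hist[best]) best = b;
    // parabolic interpolation around the peak
    double hl = hist[(best + 35) % 36], hc = hist[best], hr = hist[(best + 1) % 36];
    double denom = hl - 2 * hc + hr;
    double off = (std::fabs(denom) > 1e-12) ? 0.5 * (hl - hr) / denom : 0.0;
    double theta = ((best + 0.5 + off) / 36.0) * 2.0 * M_PI - M_PI;
    ori[i] = theta;
    double ct = std::cos(theta), st = std::sin(theta);
    // --- 4x4 spatial x 8 orientation histogram over a rotated 16x16 grid ---
    double d[128] = {0};
    double dsig = 8.0;  // in sample units (half the 16-sample window)
    bool oob = false;
    for (int sy = 0; sy < 16; ++sy) {
      for (int sx = 0; sx < 16; ++sx) {
        double u = (sx - 7.5) * ks;   // un-rotated offsets in pixels
        double v = (sy - 7.5) * ks;
        double px = kx + ct * u - st * v;
        double py = ky + st * u + ct * v;
        if (px < 1 || px > w - 2 || py < 1 || py > h - 2) { continue; }
        double gx, gy;
        grad_at(img, px, py, gx, gy);
        // rotate gradient into the keypoint frame
        double rgx = ct * gx + st * gy;
        double rgy = -st * gx + ct * gy;
        double mag = std::sqrt(rgx * rgx + rgy * rgy);
        if (mag <= 0) continue;
        double du = (sx - 7.5) / 16.0, dv = (sy - 7.5) / 16.0;
        double wgt = std::exp(-0.5 * ((sx - 7.5) * (sx - 7.5) +
                                      (sy - 7.5) * (sy - 7.5)) / (dsig * dsig));
        double ang = std::atan2(rgy, rgx) + M_PI;       // [0, 2pi)
        double obin = ang / (2.0 * M_PI) * 8.0;
        double xb = (sx + 0.5) / 4.0 - 0.5;             // [−0.5, 3.5)
        double yb = (sy + 0.5) / 4.0 - 0.5;
        // trilinear soft-binning
        int x0 = (int)std::floor(xb), y0 = (int)std::floor(yb);
        int o0 = (int)std::floor(obin);
        double fx = xb - x0, fy = yb - y0, fo = obin - o0;
        for (int bx = 0; bx <= 1; ++bx) {
          int xi = x0 + bx;
          if (xi < 0 || xi > 3) continue;
          double wx = bx ? fx : 1 - fx;
          for (int by = 0; by <= 1; ++by) {
            int yi = y0 + by;
            if (yi < 0 || yi > 3) continue;
            double wy = by ? fy : 1 - fy;
            for (int bo = 0; bo <= 1; ++bo) {
              int oi = (o0 + bo) % 8;
              double wo = bo ? fo : 1 - fo;
              d[(yi * 4 + xi) * 8 + oi] += wgt * mag * wx * wy * wo;
            }
          }
        }
        (void)du; (void)dv;
      }
    }
    double nrm = 0;
    for (int j = 0; j < 128; ++j) nrm += d[j] * d[j];
    nrm = std::sqrt(nrm);
    if (nrm < 1e-9) { keep[i] = false; continue; }
    for (int j = 0; j < 128; ++j) {
      d[j] /= nrm;
      if (d[j] > 0.2) d[j] = 0.2;  // illumination robustness clip
    }
    nrm = 0;
    for (int j = 0; j < 128; ++j) nrm += d[j] * d[j];
    nrm = std::sqrt(nrm);
    for (int j = 0; j < 128; ++j) desc(i, j) = d[j] / nrm;
    keep[i] = true;
    (void)oob;
  }
  return List::create(_["descriptors"] = desc, _["orientations"] = ori,
                      _["keep"] = keep);
}
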