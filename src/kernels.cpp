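#include <Rcpp.h>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Reflect index into [0, n-1] (mirror without repeating the edge pixel,
// falling back to clamping for tiny images).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Windowed rank transform: out(q) = 255 * (c(q) / h^2)^r where c(q) counts
// pixels q' in the h x h window around q with I(q) - I(q') > 0 (center
// included in the window; it never counts itself since the difference is 0).
// Borders use reflection padding.
// [[Rcpp::export(name = ".ahe_cpp")]]
NumericMatrix ahe_cpp(NumericMatrix img, int h, double r) {
  const int H = img.nrow(), W = img.ncol();
  const int k = h / 2;
  const double denom = (double)h * (double)h;
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      const double c0 = img(y, x);
      int cnt = 0;
      for (int dx = -k; dx <= k; ++dx) {
        const int xx = reflect(x + dx, W);
        for (int dy = -k; dy <= k; ++dy) {
          const int yy = reflect(y + dy, H);
          if (c0 - img(yy, xx) > 0.0) ++cnt;
        }
      }
      out(y, x) = 255.0 * std::pow((double)cnt / denom, r);
    }
  }
  return out;
}

// Exact squared Euclidean distance transform (Felzenszwalb-Huttenlocher),
// 1-D lower envelope of parabolas.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d,
                   std::vector<int>& arg, int n) {
  const double INF = std::numeric_limits<double>::infinity();
  // only finite parabolas take part in the lower envelope
  std::vector<int> idx;
  idx.reserve(n);
  for (int q = 0; q < n; ++q) if (std::isfinite(f[q])) idx.push_back(q);
  if (idx.empty()) {
    for (int q = 0; q < n; ++q) { d[q] = INF; arg[q] = -1; }
    return;
  }
  const int m = (int)idx.size();
  std::vector<int> v(m);
  std::vector<double> z(m + 1);
  int kk = 0;
  v[0] = idx[0];
  z[0] = -INF;
  z[1] = INF;
  for (int j = 1; j < m; ++j) {
    const int q = idx[j];
    double s;
    while (true) {
      const int p = v[kk];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * (q - p));
      if (kk > 0 && s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (z[kk + 1] < q) ++kk;
    const int p = v[kk];
    d[q] = (q - p) * (double)(q - p) + f[p];
    arg[q] = p;
  }
}

// Distance of each TRUE pixel to the nearest FALSE pixel; 0 on FALSE pixels.
// Returns list(dist = Euclidean distances, nearest = 1-based linear index of
// the nearest FALSE pixel, or NA when the mask has no FALSE pixel).
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  // Phase 1: per column, nearest background row.
  std::vector<double> D(H * (size_t)W);
  std::vector<int> site_row(H * (size_t)W, -1);
  std::vector<double> f(std::max(H, W));
  std::vector<double> d(std::max(H, W));
  std::vector<int> arg(std::max(H, W));
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) f[y] = mask(y, x) ? INF : 0.0;
    edt_1d(f, d, arg, H);
    for (int y = 0; y < H; ++y) {
      D[y + (size_t)x * H] = d[y];
      // arg[y] is the row minimizing (y-p)^2 + f[p]; meaningful iff finite
      site_row[y + (size_t)x * H] = std::isfinite(d[y]) ? arg[y] : -1;
    }
  }
  // Phase 2: per row, lower envelope across columns.
  NumericMatrix dist(H, W);
  IntegerMatrix nearest(H, W);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = D[y + (size_t)x * H];
    edt_1d(f, d, arg, W);
    for (int x = 0; x < W; ++x) {
      dist(y, x) = std::isfinite(d[x]) ? std::sqrt(d[x]) : NA_REAL;
      const int cx = arg[x];
      const int ry = std::isfinite(d[x]) ? site_row[y + (size_t)cx * H] : -1;
      nearest(y, x) = (ry >= 0) ? (ry + cx * H + 1) : NA_INTEGER;
    }
  }
  return List::create(_["dist"] = dist, _["nearest"] = nearest);
}

// Binary erosion/dilation over an arbitrary footprint given as 0-based
// (dy, dx) offsets. Outside the image counts as background.
// [[Rcpp::export(name = ".morph_cpp")]]
LogicalMatrix morph_cpp(LogicalMatrix mask, IntegerVector dy, IntegerVector dx,
                        bool dilate) {
  const int H = mask.nrow(), W = mask.ncol();
  const int m = dy.size();
  LogicalMatrix out(H, W);
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      bool v = !dilate;  // erosion: AND-identity; dilation: OR-identity
      for (int j = 0; j < m; ++j) {
        const int yy = y + dy[j], xx = x + dx[j];
        const bool inside = yy >= 0 && yy < H && xx >= 0 && xx < W;
        const bool pix = inside ? (bool)mask(yy, xx) : false;
        if (dilate) { if (pix) { v = true; break; } }
        else        { if (!pix) { v = false; break; } }
      }
      out(y, x) = v;
    }
  }
  return out;
}

// 8-connected component labelling by breadth-first search; labels are
// consecutive 1..n in raster order of each component's first pixel.
// [[Rcpp::export(name = ".label_cpp")]]
List label_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> sizes;
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      int sz = 0;
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        ++sz;
        const int py = p % H, px = p / H;
        for (int dx2 = -1; dx2 <= 1; ++dx2) {
          for (int dy2 = -1; dy2 <= 1; ++dy2) {
            if (dx2 == 0 && dy2 == 0) continue;
            const int yy = py + dy2, xx = px + dx2;
            if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
            if (mask(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              stack.push_back(yy + xx * H);
            }
          }
        }
      }
      sizes.push_back(sz);
    }
  }
  return List::create(_["labels"] = lab, _["n"] = next,
                      _["sizes"] = IntegerVector(sizes.begin(), sizes.end()));
}
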