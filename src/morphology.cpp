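// Low-level image primitives used by segmentation, EDF and the ROI/ZIP
// writers. Images are R matrices indexed [row, col] = [y, x], column-major.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 4-connected labeling of a binary mask (non-zero = foreground).
// Labels are contiguous 1..N in scan order of first contact.
// [[Rcpp::export]]
IntegerMatrix cp_label_components(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        const int dr[4] = {-1, 1, 0, 0};
        const int dc[4] = {0, 0, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int rr = cr + dr[k], cch = cc + dc[k];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) != 0 && lab(rr, cch) == 0) {
            lab(rr, cch) = next;
            stack.push_back(rr + cch * nr);
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Felzenszwalb-Huttenlocher 1D squared distance transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance of each foreground pixel to
// the nearest background (zero) pixel.
// [[Rcpp::export]]
NumericMatrix cp_distance_transform(const IntegerMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      d(r, c) = mask(r, c) != 0 ? INF : 0.0;
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {            // columns first
    for (int r = 0; r < nr; ++r) f[r] = d(r, c);
    f.resize(nr); out.resize(nr);
    dt1d(f, out);
    for (int r = 0; r < nr; ++r) d(r, c) = out[r];
  }
  for (int r = 0; r < nr; ++r) {            // then rows
    f.resize(nc); out.resize(nc);
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, out);
    for (int c = 0; c < nc; ++c) d(r, c) = std::sqrt(out[c]);
  }
  return d;
}

// Grayscale morphological reconstruction by dilation (marker <= mask),
// hybrid raster/anti-raster sweeps followed by a FIFO pass (Vincent 1993).
// [[Rcpp::export]]
NumericMatrix cp_reconstruct(const NumericMatrix& marker,
                             const NumericMatrix& maskimg) {
  const int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(clone(marker));
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  // raster
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      // N+ neighbours (already visited in column-major raster order)
      const int drp[4] = {-1, -1, 0, 1};
      const int dcp[4] = {0, -1, -1, -1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, maskimg(r, c));
    }
  // anti-raster + queue
  std::queue<int> fifo;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      const int drp[4] = {1, 1, 0, -1};
      const int dcp[4] = {0, 1, 1, 1};
      for (int k = 0; k < 4; ++k) {
        int rr = r + drp[k], cc = c + dcp[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) > m) m = J(rr, cc);
      }
      J(r, c) = std::min(m, maskimg(r, c));
      for (int k = 0; k < 8; ++k) {
        int rr = r + dr8[k], cc = c + dc8[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        if (J(rr, cc) < J(r, c) && J(rr, cc) < maskimg(rr, cc)) {
          fifo.push(r + c * nr);
          break;
        }
      }
    }
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx % nr, c = idx / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr8[k], cc = c + dc8[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (J(rr, cc) < J(r, c) && maskimg(rr, cc) != J(rr, cc)) {
        double v = std::min(J(r, c), maskimg(rr, cc));
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(rr + cc * nr);
        }
      }
    }
  }
  return J;
}

struct WsPix {
  double prio;
  long order;
  int idx;
};
struct WsCmp {
  bool operator()(const WsPix& a, const WsPix& b) const {
    if (a.prio != b.prio) return a.prio < b.prio;   // max-heap on priority
    return a.order > b.order;                        // FIFO tie-break
  }
};

// Seeded watershed: grow labelled seeds over mask in order of decreasing
// priority (e.g. a distance transform). Unseeded mask pixels join the
// first region that reaches them; regions never merge.
// [[Rcpp::export]]
IntegerMatrix cp_watershed(const NumericMatrix& priority,
                           const IntegerMatrix& seeds,
                           const IntegerMatrix& mask) {
  const int nr = priority.nrow(), nc = priority.ncol();
  IntegerMatrix lab(clone(seeds));
  std::priority_queue<WsPix, std::vector<WsPix>, WsCmp> pq;
  long ord = 0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0)
        for (int k = 0; k < 4; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0)
            pq.push({priority(rr, cc), ord++, rr + cc * nr});
        }
  while (!pq.empty()) {
    WsPix p = pq.top(); pq.pop();
    int r = p.idx % nr, c = p.idx / nr;
    if (lab(r, c) != 0) continue;
    int chosen = 0;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (lab(rr, cc) > 0) { chosen = lab(rr, cc); break; }
    }
    if (chosen == 0) continue;
    lab(r, c) = chosen;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (mask(rr, cc) != 0 && lab(rr, cc) == 0)
        pq.push({priority(rr, cc), ord++, rr + cc * nr});
    }
  }
  return lab;
}

// Square median filter of an integer image (radius px each side).
// [[Rcpp::export]]
IntegerMatrix cp_median_filter(const IntegerMatrix& img, int radius) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<int> win;
  win.reserve((2 * radius + 1) * (2 * radius + 1));
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      win.clear();
      for (int cc = std::max(0, c - radius); cc <= std::min(nc - 1, c + radius); ++cc)
        for (int rr = std::max(0, r - radius); rr <= std::min(nr - 1, r + radius); ++rr)
          win.push_back(img(rr, cc));
      size_t mid = win.size() / 2;
      std::nth_element(win.begin(), win.begin() + mid, win.end());
      out(r, c) = win[mid];
    }
  return out;
}

// Moore-neighbour boundary trace of one label. Returns an n x 2 matrix of
// 0-based (x, y) pixel coordinates, clockwise, starting at the topmost of
// the leftmost boundary pixels.
// [[Rcpp::export]]
IntegerMatrix cp_trace_boundary(const IntegerMatrix& labels, int label) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int sr = -1, sc = -1;
  for (int c = 0; c < nc && sr < 0; ++c)
    for (int r = 0; r < nr; ++r)
      if (labels(r, c) == label) { sr = r; sc = c; break; }
  if (sr < 0) return IntegerMatrix(0, 2);
  // Moore neighbourhood, clockwise starting from W
  const int mdr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mdc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  std::vector<std::pair<int,int>> path;
  int r = sr, c = sc;
  int back = 0;  // we entered from the West (background to the left)
  path.push_back({r, c});
  for (int guard = 0; guard < 8 * nr * nc; ++guard) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int dir = (back + k) % 8;
      int rr = r + mdr[dir], cc = c + mdc[dir];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) == label) { found = dir; r = rr; c = cc; break; }
    }
    if (found < 0) break;                 // isolated pixel
    if (r == sr && c == sc) break;        // closed the loop
    path.push_back({r, c});
    back = (found + 4) % 8;               // direction pointing back where we came from
  }
  IntegerMatrix out((int)path.size(), 2);
  for (size_t i = 0; i < path.size(); ++i) {
    out((int)i, 0) = path[i].second;  // x = col
    out((int)i, 1) = path[i].first;   // y = row
  }
  return out;
}

// CRC-32 (IEEE, as used by ZIP) of a raw vector.
// [[Rcpp::export]]
double cp_crc32(const RawVector& bytes) {
  static uint32_t table[256];
  static bool init = false;
  if (!init) {
    for (uint32_t i = 0; i < 256; ++i) {
      uint32_t crc = i;
      for (int j = 0; j < 8; ++j)
        crc = (crc & 1) ? (0xEDB88320u ^ (crc >> 1)) : (crc >> 1);
      table[i] = crc;
    }
    init = true;
  }
  uint32_t crc = 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < bytes.size(); ++i)
    crc = table[(crc ^ bytes[i]) & 0xFFu] ^ (crc >> 8);
  return (double)(crc ^ 0xFFFFFFFFu);
}

// Separable convolution with reflective (mirror) boundary handling.
// kr filters along rows (y), kc along columns (x); both odd-length.
// [[Rcpp::export]]
NumericMatrix cp_convolve_sep(const NumericMatrix& img,
                              const NumericVector& kr,
                              const NumericVector& kc) {
  const int nr = img.nrow(), nc = img.ncol();
  const int hr = (kr.size() - 1) / 2, hc = (kc.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  auto refl = [](int i, int n) {
    if (n == 1) return 0;
    int p = 2 * (n - 1);
    i = ((i % p) + p) % p;
    return i < n ? i : p - i;
  };
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -hr; k <= hr; ++k)
        s += kr[k + hr] * img(refl(r + k, nr), c);
      tmp(r, c) = s;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      for (int k = -hc; k <= hc; ++k)
        s += kc[k + hc] * tmp(r, refl(c + k, nc));
      out(r, c) = s;
    }
  return out;
}
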