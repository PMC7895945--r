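// Low-level 3D image operations for nucleus segmentation.
// All arrays use R's column-major layout with dim = c(nz, ny, nx):
// linear index idx = z + nz*(y + ny*x).  "Raster order" below means
// ascending linear index in this layout; it is the documented,
// deterministic tie-break for flooding and plateau handling.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline void offsets26(int nz, int ny, std::vector<int>& off,
                             std::vector<int>& dz, std::vector<int>& dy,
                             std::vector<int>& dx) {
  for (int ax = -1; ax <= 1; ++ax)
    for (int ay = -1; ay <= 1; ++ay)
      for (int az = -1; az <= 1; ++az) {
        if (ax == 0 && ay == 0 && az == 0) continue;
        off.push_back(az + nz * (ay + ny * ax));
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
}

// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> off, dz, dy, dx;
  offsets26(nz, ny, off, dz, dy, dx);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++cur;
    stack.clear();
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v % nz);
      int y = (int)((v / nz) % ny);
      int x = (int)(v / ((R_xlen_t)nz * ny));
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t w = v + off[k];
        if (mask[w] && lab[w] == 0) { lab[w] = cur; stack.push_back(w); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

struct QEntry {
  double p;
  R_xlen_t idx;
  int label;
  std::uint64_t order;
};
struct QCompare {
  // max-heap on probability; ties: lower raster index, then earlier push
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.p != b.p) return a.p < b.p;
    if (a.idx != b.idx) return a.idx > b.idx;
    return a.order > b.order;
  }
};

// Seeded watershed by priority flooding on the probability landscape,
// restricted to mask voxels.  Voxels unreachable from any seed stay 0.
// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector prob, IntegerVector seeds,
                            LogicalVector mask, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n, 0);
  std::vector<int> off, dz, dy, dx;
  offsets26(nz, ny, off, dz, dy, dx);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  std::uint64_t order = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      lab[i] = seeds[i];
      pq.push(QEntry{prob[i], i, seeds[i], order++});
    }
  }
  while (!pq.empty()) {
    QEntry e = pq.top(); pq.pop();
    R_xlen_t v = e.idx;
    int z = (int)(v % nz);
    int y = (int)((v / nz) % ny);
    int x = (int)(v / ((R_xlen_t)nz * ny));
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      R_xlen_t w = v + off[k];
      if (mask[w] && lab[w] == 0) {
        lab[w] = lab[v];
        pq.push(QEntry{prob[w], w, lab[v], order++});
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// 2D local maxima with noise tolerance h on one image plane (ny x nx,
// column-major idx = y + ny*x).  A candidate is a pixel >= all 8
// neighbours with value >= t_fg.  Candidates are processed in
// (value desc, index asc) order; each claims the connected region of
// pixels with value > v - h.  A candidate whose region touches an
// already-claimed pixel is merged into that earlier (higher) maximum
// and dropped.  Returns 0-based indices of accepted maxima.
// [[Rcpp::export]]
IntegerVector cpp_find_maxima_2d(NumericVector plane, int ny, int nx,
                                 double h, double t_fg) {
  const R_xlen_t n = (R_xlen_t)ny * nx;
  std::vector<R_xlen_t> cand;
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = plane[i];
    if (v < t_fg) continue;
    int y = (int)(i % ny), x = (int)(i / ny);
    bool ismax = true;
    for (int ax = -1; ax <= 1 && ismax; ++ax)
      for (int ay = -1; ay <= 1; ++ay) {
        if (ax == 0 && ay == 0) continue;
        int yy = y + ay, xx = x + ax;
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        if (plane[yy + (R_xlen_t)ny * xx] > v) { ismax = false; break; }
      }
    if (ismax) cand.push_back(i);
  }
  std::sort(cand.begin(), cand.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (plane[a] != plane[b]) return plane[a] > plane[b];
    return a < b;
  });
  std::vector<int> owner(n, 0);        // 0 = unclaimed, else candidate rank
  std::vector<R_xlen_t> region, stack;
  std::vector<int> accepted;
  int rank = 0;
  for (R_xlen_t c : cand) {
    ++rank;
    if (owner[c] != 0) continue;       // merged into a higher maximum
    double lim = plane[c] - h;
    bool reject = false;
    region.clear(); stack.clear();
    stack.push_back(c);
    owner[c] = rank;
    region.push_back(c);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int y = (int)(v % ny), x = (int)(v / ny);
      for (int ax = -1; ax <= 1; ++ax)
        for (int ay = -1; ay <= 1; ++ay) {
          if (ax == 0 && ay == 0) continue;
          int yy = y + ay, xx = x + ax;
          if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
          R_xlen_t w = yy + (R_xlen_t)ny * xx;
          if (plane[w] <= lim) continue;
          if (owner[w] != 0 && owner[w] != rank) { reject = true; continue; }
          if (owner[w] == 0) {
            owner[w] = rank;
            region.push_back(w);
            stack.push_back(w);
          }
        }
    }
    if (reject) {
      for (R_xlen_t w : region) owner[w] = 0;  // release; claimed elsewhere
    } else {
      accepted.push_back((int)c);
    }
  }
  return wrap(accepted);
}

// Brute-force 3D nearest-neighbour distances (n x 3 coordinate matrix).
// [[Rcpp::export]]
NumericVector cpp_nn_distances(NumericMatrix pts) {
  const int n = pts.nrow();
  NumericVector out(n);
  if (n < 2) stop("need at least 2 points");
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Minimum pairwise distance (hard-core check); returns Inf for n < 2.
// [[Rcpp::export]]
double cpp_min_pairwise_distance(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 2) return R_PosInf;
  double best = R_PosInf;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - pts(i, 0);
      double dy = pts(j, 1) - pts(i, 1);
      double dz = pts(j, 2) - pts(i, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

static inline double det4(double m[4][4]) {
  // cofactor expansion along the first row with 3x3 minors
  double out = 0.0;
  for (int c = 0; c < 4; ++c) {
    double sub[3][3];
    for (int i = 1; i < 4; ++i) {
      int cc = 0;
      for (int j = 0; j < 4; ++j) {
        if (j == c) continue;
        sub[i - 1][cc++] = m[i][j];
      }
    }
    double minor =
      sub[0][0] * (sub[1][1] * sub[2][2] - sub[1][2] * sub[2][1]) -
      sub[0][1] * (sub[1][0] * sub[2][2] - sub[1][2] * sub[2][0]) +
      sub[0][2] * (sub[1][0] * sub[2][1] - sub[1][1] * sub[2][0]);
    out += ((c % 2) ? -1.0 : 1.0) * m[0][c] * minor;
  }
  return out;
}

// Batch in-circumsphere test: for each positively oriented tetrahedron
// (rows of 1-based vertex indices), is point p strictly inside its
// circumsphere?  Uses the standard lifted 4x4 determinant predicate.
// [[Rcpp::export]]
LogicalVector cpp_insphere_batch(NumericMatrix coords, IntegerMatrix tets,
                                 NumericVector p) {
  const int T = tets.nrow();
  LogicalVector out(T);
  for (int t = 0; t < T; ++t) {
    double m[4][4];
    for (int v = 0; v < 4; ++v) {
      int i = tets(t, v) - 1;
      double dx = coords(i, 0) - p[0];
      double dy = coords(i, 1) - p[1];
      double dz = coords(i, 2) - p[2];
      m[v][0] = dx; m[v][1] = dy; m[v][2] = dz;
      m[v][3] = dx * dx + dy * dy + dz * dz;
    }
    // with det3(b-a, c-a, d-a) > 0 orientation, inside <=> det4 < 0
    out[t] = det4(m) < 0.0;
  }
  return out;
}
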