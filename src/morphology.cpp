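// 3D binary morphology, connected components, geodesic reconstruction and
// grid resampling on R arrays stored column-major with dim = (nz, ny, nx).
// Linear index of voxel (i, j, k) is i + nz*j + nz*ny*k (0-based).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Grid {
  int n1, n2, n3;     // dim[0], dim[1], dim[2]
  R_xlen_t n;
  Grid(IntegerVector dim) : n1(dim[0]), n2(dim[1]), n3(dim[2]) {
    n = (R_xlen_t)n1 * n2 * n3;
  }
  inline R_xlen_t idx(int i, int j, int k) const {
    return (R_xlen_t)i + (R_xlen_t)n1 * j + (R_xlen_t)n1 * n2 * k;
  }
};

// Neighbourhood offset table. conn: 6 (face), 26 (full), 4 / 8 (in-plane,
// i.e. within a fixed first-axis slice).
std::vector<std::array<int,3>> offsets(int conn) {
  std::vector<std::array<int,3>> off;
  if (conn == 6) {
    off = {{{1,0,0}},{{-1,0,0}},{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else if (conn == 26) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          if (a || b || c) off.push_back({{a,b,c}});
  } else if (conn == 4) {
    off = {{{0,1,0}},{{0,-1,0}},{{0,0,1}},{{0,0,-1}}};
  } else if (conn == 8) {
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c)
        if (b || c) off.push_back({{0,b,c}});
  } else {
    stop("unsupported connectivity: %d", conn);
  }
  return off;
}

// Multi-source BFS chamfer distance from the foreground, where one BFS layer
// equals one dilation step with the given structuring element.
void bfs_distance(const LogicalVector& x, const Grid& g,
                  const std::vector<std::array<int,3>>& off,
                  int max_steps, std::vector<int>& dist) {
  dist.assign(g.n, -1);
  std::queue<R_xlen_t> q;
  for (R_xlen_t v = 0; v < g.n; ++v)
    if (x[v]) { dist[v] = 0; q.push(v); }
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    if (dist[v] >= max_steps) continue;
    int k = (int)(v / ((R_xlen_t)g.n1 * g.n2));
    int r = (int)(v % ((R_xlen_t)g.n1 * g.n2));
    int j = r / g.n1, i = r % g.n1;
    for (auto& o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 || kk >= g.n3)
        continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".cg_dilate")]]
LogicalVector cg_dilate(LogicalVector x, IntegerVector dim, int steps, int conn) {
  Grid g(dim);
  if (steps < 0) stop("steps must be >= 0");
  LogicalVector out(g.n);
  out.attr("dim") = dim;
  if (steps == 0) { for (R_xlen_t v = 0; v < g.n; ++v) out[v] = x[v]; return out; }
  auto off = offsets(conn);
  std::vector<int> dist;
  bfs_distance(x, g, off, steps, dist);
  for (R_xlen_t v = 0; v < g.n; ++v)
    out[v] = (dist[v] >= 0 && dist[v] <= steps);
  return out;
}

// [[Rcpp::export(name = ".cg_erode")]]
LogicalVector cg_erode(LogicalVector x, IntegerVector dim, int steps, int conn,
                       bool pad_foreground) {
  // erosion by duality; voxels outside the grid count as background, so the
  // border erodes (standard zero-padded convention)
  Grid g(dim);
  LogicalVector inv(g.n);
  for (R_xlen_t v = 0; v < g.n; ++v) inv[v] = !x[v];
  // pad effect: treat out-of-grid as background by seeding border distances
  auto off = offsets(conn);
  std::vector<int> dist;
  // distance from complement, with out-of-grid handled as complement: seed
  // border voxels of the foreground at their step count via a virtual layer.
  // Simplest correct approach: distance from (complement union virtual
  // out-of-grid). Implement by computing distance from complement and from
  // grid border separately.
  bfs_distance(inv, g, off, steps, dist);
  std::vector<int> bdist(g.n, -1);
  if (!pad_foreground) {
    std::queue<R_xlen_t> q;
    for (int k = 0; k < g.n3; ++k)
      for (int j = 0; j < g.n2; ++j)
        for (int i = 0; i < g.n1; ++i)
          if (i == 0 || j == 0 || k == 0 || i == g.n1 - 1 || j == g.n2 - 1 ||
              k == g.n3 - 1) {
            R_xlen_t v = g.idx(i, j, k);
            bdist[v] = 1;  // one step from the virtual outside layer
            q.push(v);
          }
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      if (bdist[v] >= steps) continue;
      int k = (int)(v / ((R_xlen_t)g.n1 * g.n2));
      int r = (int)(v % ((R_xlen_t)g.n1 * g.n2));
      int j = r / g.n1, i = r % g.n1;
      for (auto& o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 || kk >= g.n3)
          continue;
        R_xlen_t w = g.idx(ii, jj, kk);
        if (bdist[w] < 0) { bdist[w] = bdist[v] + 1; q.push(w); }
      }
    }
  }
  LogicalVector out(g.n);
  out.attr("dim") = dim;
  for (R_xlen_t v = 0; v < g.n; ++v) {
    bool eaten = (dist[v] >= 0 && dist[v] <= steps) ||
                 (bdist[v] >= 0 && bdist[v] <= steps);
    out[v] = x[v] && !eaten;
  }
  return out;
}

// [[Rcpp::export(name = ".cg_label")]]
IntegerVector cg_label(LogicalVector x, IntegerVector dim, int conn) {
  Grid g(dim);
  auto off = offsets(conn);
  IntegerVector lab(g.n);
  lab.attr("dim") = dim;
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < g.n; ++s) {
    if (!x[s] || lab[s]) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int k = (int)(v / ((R_xlen_t)g.n1 * g.n2));
      int r = (int)(v % ((R_xlen_t)g.n1 * g.n2));
      int j = r / g.n1, i = r % g.n1;
      for (auto& o : off) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 || kk >= g.n3)
          continue;
        R_xlen_t w = g.idx(ii, jj, kk);
        if (x[w] && !lab[w]) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Geodesic reconstruction (by dilation) of seed within mask.
// [[Rcpp::export(name = ".cg_reconstruct")]]
LogicalVector cg_reconstruct(LogicalVector seed, LogicalVector mask,
                             IntegerVector dim, int conn) {
  Grid g(dim);
  auto off = offsets(conn);
  LogicalVector out(g.n);
  out.attr("dim") = dim;
  std::queue<R_xlen_t> q;
  for (R_xlen_t v = 0; v < g.n; ++v)
    if (seed[v] && mask[v]) { out[v] = true; q.push(v); }
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int k = (int)(v / ((R_xlen_t)g.n1 * g.n2));
    int r = (int)(v % ((R_xlen_t)g.n1 * g.n2));
    int j = r / g.n1, i = r % g.n1;
    for (auto& o : off) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= g.n1 || jj >= g.n2 || kk >= g.n3)
        continue;
      R_xlen_t w = g.idx(ii, jj, kk);
      if (mask[w] && !out[w]) { out[w] = true; q.push(w); }
    }
  }
  return out;
}

// Separable Gaussian filter with hard truncation radius (in voxels).
// Kernel weights exp(-d^2 / (2 sigma^2)) for |d| <= radius, normalised.
// [[Rcpp::export(name = ".cg_gaussian3d")]]
NumericVector cg_gaussian3d(NumericVector x, IntegerVector dim, double sigma,
                            int radius) {
  Grid g(dim);
  if (sigma <= 0 || radius < 1) {
    NumericVector out = clone(x);
    out.attr("dim") = dim;
    return out;
  }
  std::vector<double> ker(2 * radius + 1);
  double s = 0;
  for (int d = -radius; d <= radius; ++d) {
    ker[d + radius] = std::exp(-(double)d * d / (2.0 * sigma * sigma));
    s += ker[d + radius];
  }
  for (auto& w : ker) w /= s;
  std::vector<double> a(x.begin(), x.end()), b(g.n);
  // pass along each axis; edges renormalised over in-grid support
  auto pass = [&](int axis) {
    int na = axis == 0 ? g.n1 : axis == 1 ? g.n2 : g.n3;
    for (int k = 0; k < g.n3; ++k)
      for (int j = 0; j < g.n2; ++j)
        for (int i = 0; i < g.n1; ++i) {
          int c = axis == 0 ? i : axis == 1 ? j : k;
          double acc = 0, wsum = 0;
          for (int d = -radius; d <= radius; ++d) {
            int cc = c + d;
            if (cc < 0 || cc >= na) continue;
            int ii = i, jj = j, kk = k;
            if (axis == 0) ii = cc; else if (axis == 1) jj = cc; else kk = cc;
            acc += ker[d + radius] * a[g.idx(ii, jj, kk)];
            wsum += ker[d + radius];
          }
          b[g.idx(i, j, k)] = acc / wsum;
        }
    std::swap(a, b);
  };
  pass(0); pass(1); pass(2);
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dim;
  return out;
}

// Resample src onto a target grid: target voxel (0-based index t) maps to
// source continuous 0-based index s = A t + b. method 0 = nearest neighbour,
// 1 = trilinear. Outside the source grid -> 0.
// [[Rcpp::export(name = ".cg_resample_affine")]]
NumericVector cg_resample_affine(NumericVector src, IntegerVector sdim,
                                 IntegerVector tdim, NumericMatrix A,
                                 NumericVector b, int method) {
  Grid gs(sdim), gt(tdim);
  NumericVector out(gt.n);
  out.attr("dim") = tdim;
  for (int k = 0; k < gt.n3; ++k)
    for (int j = 0; j < gt.n2; ++j)
      for (int i = 0; i < gt.n1; ++i) {
        double s0 = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double s1 = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double s2 = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        double val = 0;
        if (method == 0) {
          int p = (int)std::lround(s0), q = (int)std::lround(s1),
              r = (int)std::lround(s2);
          if (p >= 0 && q >= 0 && r >= 0 && p < gs.n1 && q < gs.n2 && r < gs.n3)
            val = src[gs.idx(p, q, r)];
        } else {
          int p0 = (int)std::floor(s0), q0 = (int)std::floor(s1),
              r0 = (int)std::floor(s2);
          double fp = s0 - p0, fq = s1 - q0, fr = s2 - r0;
          for (int dp = 0; dp <= 1; ++dp)
            for (int dq = 0; dq <= 1; ++dq)
              for (int dr = 0; dr <= 1; ++dr) {
                int p = p0 + dp, q = q0 + dq, r = r0 + dr;
                if (p < 0 || q < 0 || r < 0 || p >= gs.n1 || q >= gs.n2 ||
                    r >= gs.n3)
                  continue;
                double w = (dp ? fp : 1 - fp) * (dq ? fq : 1 - fq) *
                           (dr ? fr : 1 - fr);
                val += w * src[gs.idx(p, q, r)];
              }
        }
        out[gt.idx(i, j, k)] = val;
      }
  return out;
}

// Label resampling with majority vote over the target voxel's source
// footprint. Target voxel t covers the source box centred at A t + b with
// half-width hw (source voxels, per axis). Majority label wins; ties take
// the lowest label; background (0) only wins if no nonzero label occurs.
// An empty box falls back to nearest neighbour.
// [[Rcpp::export(name = ".cg_resample_labels_majority")]]
IntegerVector cg_resample_labels_majority(IntegerVector src, IntegerVector sdim,
                                          IntegerVector tdim, NumericMatrix A,
                                          NumericVector b, NumericVector hw) {
  Grid gs(sdim), gt(tdim);
  IntegerVector out(gt.n);
  out.attr("dim") = tdim;
  std::map<int,int> cnt;
  for (int k = 0; k < gt.n3; ++k)
    for (int j = 0; j < gt.n2; ++j)
      for (int i = 0; i < gt.n1; ++i) {
        double s0 = A(0,0)*i + A(0,1)*j + A(0,2)*k + b[0];
        double s1 = A(1,0)*i + A(1,1)*j + A(1,2)*k + b[1];
        double s2 = A(2,0)*i + A(2,1)*j + A(2,2)*k + b[2];
        int lo0 = (int)std::ceil(s0 - hw[0]), hi0 = (int)std::floor(s0 + hw[0]);
        int lo1 = (int)std::ceil(s1 - hw[1]), hi1 = (int)std::floor(s1 + hw[1]);
        int lo2 = (int)std::ceil(s2 - hw[2]), hi2 = (int)std::floor(s2 + hw[2]);
        cnt.clear();
        for (int p = std::max(lo0, 0); p <= std::min(hi0, gs.n1 - 1); ++p)
          for (int q = std::max(lo1, 0); q <= std::min(hi1, gs.n2 - 1); ++q)
            for (int r = std::max(lo2, 0); r <= std::min(hi2, gs.n3 - 1); ++r)
              cnt[src[gs.idx(p, q, r)]]++;
        int lab = 0;
        if (cnt.empty()) {
          int p = (int)std::lround(s0), q = (int)std::lround(s1),
              r = (int)std::lround(s2);
          if (p >= 0 && q >= 0 && r >= 0 && p < gs.n1 && q < gs.n2 && r < gs.n3)
            lab = src[gs.idx(p, q, r)];
        } else {
          // std::map iterates labels in ascending order, so requiring a
          // strictly greater count leaves the lowest label holding any tie
          int best = -1;
          for (auto& kv : cnt)
            if (kv.second > best) { best = kv.second; lab = kv.first; }
        }
        out[gt.idx(i, j, k)] = lab;
      }
  return out;
}
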