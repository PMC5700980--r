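#include <Rcpp.h>
#include <queue>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// 3D connected-component labeling on a sparse foreground.
//
// dims: array extents (d0, d1, d2) in R's column-major order, i.e. a voxel
// (i, j, k) (0-based) has linear index i + d0 * (j + d1 * k).
// fg: 0-based linear indices of foreground voxels.
// connectivity: 6 (faces) or 26 (faces + edges + corners).
// Returns a label (1..K) for every foreground voxel, in input order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector dims, IntegerVector fg,
                                   int connectivity) {
  const int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  const int n = fg.size();
  std::unordered_map<long long, int> pos;
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) pos[(long long)fg[i]] = i;

  IntegerVector labels(n, 0);
  int next_label = 0;
  std::queue<int> q;

  for (int s = 0; s < n; ++s) {
    if (labels[s] != 0) continue;
    labels[s] = ++next_label;
    q.push(s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      long long idx = fg[cur];
      int i = (int)(idx % d0);
      int rest = (int)(idx / d0);
      int j = rest % d1;
      int k = rest / d1;
      for (int dk = -1; dk <= 1; ++dk) {
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int nb_order = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && nb_order > 1) continue;
            int ni = i + di, nj = j + dj, nk = k + dk;
            if (ni < 0 || ni >= d0 || nj < 0 || nj >= d1 ||
                nk < 0 || nk >= d2) continue;
            long long nidx = ni + (long long)d0 * (nj + (long long)d1 * nk);
            auto it = pos.find(nidx);
            if (it == pos.end()) continue;
            int p = it->second;
            if (labels[p] == 0) { labels[p] = next_label; q.push(p); }
          }
        }
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// Bounded Voronoi tessellation by incremental half-plane clipping.
//
// Each seed's cell starts as the bounding rectangle and is clipped by the
// perpendicular bisector of (seed, candidate) for candidates gathered in
// rings of a uniform grid, nearest first.  A candidate at distance d can
// only modify the cell if d < 2 * (max distance from seed to any current
// vertex), which gives an exact early-termination rule.  Edge provenance is
// tracked through the clipping so true Voronoi neighbors are recovered.

struct Poly {
  std::vector<double> x, y;
  std::vector<int> tag;  // tag of edge leaving vertex i (negative: box edge)
};

static void clip_halfplane(Poly &p, double nx, double ny, double mx,
                           double my, int j) {
  const int n = (int)p.x.size();
  if (n == 0) return;
  Poly out;
  out.x.reserve(n + 2); out.y.reserve(n + 2); out.tag.reserve(n + 2);
  std::vector<double> f(n);
  for (int i = 0; i < n; ++i)
    f[i] = nx * (p.x[i] - mx) + ny * (p.y[i] - my);
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    double fc = f[i], fn = f[i2];
    if (fc <= 0.0) {
      out.x.push_back(p.x[i]); out.y.push_back(p.y[i]);
      out.tag.push_back(p.tag[i]);
      if (fn > 0.0) {
        double t = fc / (fc - fn);
        out.x.push_back(p.x[i] + t * (p.x[i2] - p.x[i]));
        out.y.push_back(p.y[i] + t * (p.y[i2] - p.y[i]));
        out.tag.push_back(j);
      }
    } else if (fn <= 0.0) {
      double t = fc / (fc - fn);
      out.x.push_back(p.x[i] + t * (p.x[i2] - p.x[i]));
      out.y.push_back(p.y[i] + t * (p.y[i2] - p.y[i]));
      out.tag.push_back(p.tag[i]);
    }
  }
  p = out;
}

static double max_vertex_dist2(const Poly &p, double sx, double sy) {
  double m = 0.0;
  for (size_t i = 0; i < p.x.size(); ++i) {
    double dx = p.x[i] - sx, dy = p.y[i] - sy;
    double d2 = dx * dx + dy * dy;
    if (d2 > m) m = d2;
  }
  return m;
}

// [[Rcpp::export]]
List cpp_voronoi(NumericVector x, NumericVector y, double xmin, double xmax,
                 double ymin, double ymax) {
  const int n = x.size();
  const double W = xmax - xmin, H = ymax - ymin;
  double h = std::sqrt(std::max(W * H / std::max(n, 1), 1e-12));
  int gx = std::max(1, (int)std::ceil(W / h));
  int gy = std::max(1, (int)std::ceil(H / h));
  std::vector<std::vector<int>> cells((size_t)gx * gy);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    int ix = std::min(gx - 1, std::max(0, (int)((x[i] - xmin) / h)));
    int iy = std::min(gy - 1, std::max(0, (int)((y[i] - ymin) / h)));
    cx[i] = ix; cy[i] = iy;
    cells[(size_t)ix + (size_t)gx * iy].push_back(i);
  }
  int max_ring = std::max(gx, gy);

  NumericVector area(n);
  List neighbors(n), polygons(n);
  std::vector<std::pair<double, int>> cand;

  for (int i = 0; i < n; ++i) {
    Poly p;
    p.x = {xmin, xmax, xmax, xmin};
    p.y = {ymin, ymin, ymax, ymax};
    p.tag = {-1, -2, -3, -4};
    double maxvd2 = max_vertex_dist2(p, x[i], y[i]);

    for (int r = 0; r <= max_ring; ++r) {
      // lower bound on distance from seed to any point in ring r
      if (r >= 2) {
        double dmin = (r - 1) * h;
        if (dmin * dmin > 4.0 * maxvd2) break;
      }
      cand.clear();
      int x0 = cx[i] - r, x1 = cx[i] + r, y0 = cy[i] - r, y1 = cy[i] + r;
      for (int iy = std::max(0, y0); iy <= std::min(gy - 1, y1); ++iy) {
        for (int ix = std::max(0, x0); ix <= std::min(gx - 1, x1); ++ix) {
          if (r > 0 && ix != x0 && ix != x1 && iy != y0 && iy != y1)
            continue;  // interior cells were handled in earlier rings
          for (int j : cells[(size_t)ix + (size_t)gx * iy]) {
            if (j == i) continue;
            double dx = x[j] - x[i], dy = y[j] - y[i];
            cand.push_back({dx * dx + dy * dy, j});
          }
        }
      }
      std::sort(cand.begin(), cand.end());
      for (auto &c : cand) {
        if (c.first > 4.0 * maxvd2) break;
        int j = c.second;
        double nx_ = x[j] - x[i], ny_ = y[j] - y[i];
        double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
        clip_halfplane(p, nx_, ny_, mx, my, j);
        maxvd2 = max_vertex_dist2(p, x[i], y[i]);
      }
    }

    const int nv = (int)p.x.size();
    double a = 0.0;
    for (int k = 0; k < nv; ++k) {
      int k2 = (k + 1) % nv;
      a += p.x[k] * p.y[k2] - p.x[k2] * p.y[k];
    }
    area[i] = 0.5 * std::fabs(a);

    std::vector<int> nb;
    for (int k = 0; k < nv; ++k)
      if (p.tag[k] >= 0) nb.push_back(p.tag[k] + 1);  // 1-based
    std::sort(nb.begin(), nb.end());
    nb.erase(std::unique(nb.begin(), nb.end()), nb.end());
    neighbors[i] = IntegerVector(nb.begin(), nb.end());

    NumericMatrix pm(nv, 2);
    for (int k = 0; k < nv; ++k) { pm(k, 0) = p.x[k]; pm(k, 1) = p.y[k]; }
    polygons[i] = pm;
  }

  return List::create(_["area"] = area, _["neighbors"] = neighbors,
                      _["polygons"] = polygons);
}

// ---------------------------------------------------------------------------
// Cumulative neighbor counts of B points around each A point at a set of
// increasing radii, plus nearest-B distance.  exclude_self skips b == a by
// index (for same-channel counts).
// [[Rcpp::export]]
List cpp_radial_counts(NumericVector ax, NumericVector ay, NumericVector bx,
                       NumericVector by, NumericVector radii,
                       bool exclude_self) {
  const int na = ax.size(), nb = bx.size(), nr = radii.size();
  IntegerMatrix counts(na, nr);
  NumericVector nearest(na, R_PosInf);
  std::vector<double> r2(nr);
  for (int k = 0; k < nr; ++k) r2[k] = radii[k] * radii[k];
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (exclude_self && i == j) continue;
      double dx = bx[j] - ax[i], dy = by[j] - ay[i];
      double d2 = dx * dx + dy * dy;
      if (d2 < nearest[i] * nearest[i]) nearest[i] = std::sqrt(d2);
      if (d2 <= r2[nr - 1]) {
        int k = (int)(std::lower_bound(r2.begin(), r2.end(), d2) - r2.begin());
        counts(i, k) += 1;
      }
    }
  }
  // counts[k] currently holds points in (r_{k-1}, r_k]; make cumulative
  for (int i = 0; i < na; ++i)
    for (int k = 1; k < nr; ++k) counts(i, k) += counts(i, k - 1);
  return List::create(_["counts"] = counts, _["nearest"] = nearest);
}
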