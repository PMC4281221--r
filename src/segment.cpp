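// Multi-resolution region-merging segmentation (Baatz-Schaepe criterion).
//
// Bottom-up pairwise merging on a region-adjacency graph.  The fusion
// cost of merging regions a and b is
//   f = (1 - shape_w) * dh_color + shape_w * dh_shape
//   dh_color = sum_b w_b * (n_m sd_m - n_a sd_a - n_b sd_b)
//   dh_shape = cmpct_w * dh_cmpct + (1 - cmpct_w) * dh_smooth
// with h_cmpct = l / sqrt(n) (l = perimeter in pixel edges, counting
// image borders and masked-out neighbors) and h_smooth = l / p_bbox
// (p_bbox = bounding-box perimeter); each h enters n-weighted, e.g.
// dh_cmpct = n_m h_m - n_a h_a - n_b h_b.  Scheduling: repeated sweeps
// of local mutual best fitting.  In a sweep every active region selects
// its cheapest neighbor (ties -> smallest region id); pairs that select
// each other with cost < scale^2 merge, the survivor keeping the
// smaller id.  Sweeps repeat until no merge happens.  Deterministic.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Region {
  bool active = false;
  int n = 0;
  double sum[8] = {0}, sumsq[8] = {0};
  double perim = 0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  std::map<int, double> nb;  // neighbor id -> shared boundary length
};

static inline double region_sd(const Region& R, int b) {
  double m = R.sum[b] / R.n;
  double v = R.sumsq[b] / R.n - m * m;
  return v > 0 ? std::sqrt(v) : 0.0;
}

struct CostCtx {
  int nbands;
  std::vector<double> w;
  double shape_w, cmpct_w;
};

static double fusion_cost(const Region& A, const Region& B, double shared,
                          const CostCtx& ctx) {
  int nm = A.n + B.n;
  double dcolor = 0;
  for (int b = 0; b < ctx.nbands; ++b) {
    double s = A.sum[b] + B.sum[b], ss = A.sumsq[b] + B.sumsq[b];
    double m = s / nm, v = ss / nm - m * m;
    double sdm = v > 0 ? std::sqrt(v) : 0.0;
    dcolor += ctx.w[b] * (nm * sdm - A.n * region_sd(A, b)
                          - B.n * region_sd(B, b));
  }
  double lm = A.perim + B.perim - 2.0 * shared;
  int rmin = std::min(A.rmin, B.rmin), rmax = std::max(A.rmax, B.rmax);
  int cmin = std::min(A.cmin, B.cmin), cmax = std::max(A.cmax, B.cmax);
  double bbm = 2.0 * ((rmax - rmin + 1) + (cmax - cmin + 1));
  double bba = 2.0 * ((A.rmax - A.rmin + 1) + (A.cmax - A.cmin + 1));
  double bbb = 2.0 * ((B.rmax - B.rmin + 1) + (B.cmax - B.cmin + 1));
  double dcmp = nm * lm / std::sqrt((double)nm)
    - A.n * A.perim / std::sqrt((double)A.n)
    - B.n * B.perim / std::sqrt((double)B.n);
  double dsmo = nm * lm / bbm - A.n * A.perim / bba - B.n * B.perim / bbb;
  double dshape = ctx.cmpct_w * dcmp + (1.0 - ctx.cmpct_w) * dsmo;
  return (1.0 - ctx.shape_w) * dcolor + ctx.shape_w * dshape;
}

// bands: nr x nc x nbands array (column-major); thematic: nr x nc
// integer matrix, value < 0 excludes a pixel (label 0 in the output);
// merges never join pixels with different thematic values.
// [[Rcpp::export]]
IntegerMatrix segment_mrs_cpp(NumericVector bands, IntegerVector dims,
                              NumericVector layer_weights, double scale,
                              double shape_weight, double cmpct_weight,
                              IntegerMatrix thematic) {
  const int nr = dims[0], nc = dims[1], nbv = dims[2];
  if (nbv > 8) stop("at most 8 bands supported");
  const int n = nr * nc;
  CostCtx ctx;
  ctx.nbands = nbv;
  ctx.w.assign(layer_weights.begin(), layer_weights.end());
  ctx.shape_w = shape_weight;
  ctx.cmpct_w = cmpct_weight;
  const double thr = scale * scale;

  std::vector<Region> reg(n);
  std::vector<int> parent(n);
  auto lin = [nr](int r, int c) { return r + c * nr; };

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = lin(r, c);
      parent[id] = id;
      if (thematic(r, c) < 0) continue;
      Region& R = reg[id];
      R.active = true;
      R.n = 1;
      for (int b = 0; b < nbv; ++b) {
        double v = bands[id + (R_xlen_t)b * n];
        R.sum[b] = v;
        R.sumsq[b] = v * v;
      }
      R.rmin = R.rmax = r;
      R.cmin = R.cmax = c;
      R.perim = 4;
      const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int r2 = r + dr[k], c2 = c + dc[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (thematic(r2, c2) != thematic(r, c)) continue;
        R.nb[lin(r2, c2)] += 1.0;
      }
    }
  }

  std::vector<int> active;
  active.reserve(n);
  for (int i = 0; i < n; ++i) if (reg[i].active) active.push_back(i);

  std::vector<int> best(n, -1);
  std::vector<double> bestcost(n, 0.0);
  bool merged = true;
  while (merged) {
    merged = false;
    for (int a : active) {
      const Region& A = reg[a];
      int bb = -1;
      double bc = R_PosInf;
      for (auto& kv : A.nb) {
        double cost = fusion_cost(A, reg[kv.first], kv.second, ctx);
        if (cost < bc) { bc = cost; bb = kv.first; }
      }
      best[a] = bb;
      bestcost[a] = bc;
    }
    std::vector<int> survivors;
    survivors.reserve(active.size());
    for (int a : active) {
      if (!reg[a].active) continue;  // merged away earlier this sweep
      int b = best[a];
      if (b > a && best[b] == a && bestcost[a] < thr) {
        Region& A = reg[a];
        Region& B = reg[b];
        double shared = A.nb[b];
        A.n += B.n;
        for (int k = 0; k < nbv; ++k) {
          A.sum[k] += B.sum[k];
          A.sumsq[k] += B.sumsq[k];
        }
        A.perim += B.perim - 2.0 * shared;
        A.rmin = std::min(A.rmin, B.rmin);
        A.rmax = std::max(A.rmax, B.rmax);
        A.cmin = std::min(A.cmin, B.cmin);
        A.cmax = std::max(A.cmax, B.cmax);
        A.nb.erase(b);
        for (auto& kv : B.nb) {
          int c2 = kv.first;
          if (c2 == a) continue;
          A.nb[c2] += kv.second;
          reg[c2].nb.erase(b);
          reg[c2].nb[a] += kv.second;
        }
        B.nb.clear();
        B.active = false;
        parent[b] = a;
        merged = true;
      }
      survivors.push_back(a);
    }
    active.swap(survivors);
  }

  // resolve union-find chains and relabel 1..K in ascending root id
  std::vector<int> root(n);
  for (int i = 0; i < n; ++i) {
    int r2 = i;
    while (parent[r2] != r2) r2 = parent[r2];
    int j = i;
    while (parent[j] != j) { int nx = parent[j]; parent[j] = r2; j = nx; }
    root[i] = r2;
  }
  std::map<int, int> relabel;
  for (int i = 0; i < n; ++i) if (reg[root[i]].active) relabel[root[i]] = 0;
  int next = 0;
  for (auto& kv : relabel) kv.second = ++next;  // ascending root id order
  IntegerMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = lin(r, c);
      out(r, c) = (thematic(r, c) < 0) ? 0 : relabel[root[id]];
    }
  }
  return out;
}
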