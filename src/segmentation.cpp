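#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Pixel grids are column-major R matrices; pixel (r, c) maps to c * nrow + r.

namespace {

struct DSU {
  std::vector<int> parent;
  explicit DSU(int n) : parent(n) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

} // namespace

// Local maxima with topographic-prominence filtering.
//
// Pixels inside `mask` are flooded in order of decreasing intensity while
// components are merged with union-find; when a component is absorbed at
// level v its prominence is summit - v.  Components that never merge keep
// prominence summit - (lowest processed level).  A maximum is retained when
// its prominence is at least `prominence`.  Plateau summits are replaced by
// the plateau pixel closest to the plateau centroid.
// [[Rcpp::export(name = ".find_maxima_cpp")]]
List find_maxima_cpp(NumericMatrix img, LogicalMatrix mask, double prominence) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("image and mask dimensions differ");

  std::vector<int> order;
  order.reserve(n);
  for (int i = 0; i < n; ++i)
    if (mask[i]) order.push_back(i);
  if (order.empty())
    return List::create(_["row"] = IntegerVector(0), _["col"] = IntegerVector(0),
                        _["value"] = NumericVector(0),
                        _["prominence"] = NumericVector(0));

  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (img[a] != img[b]) return img[a] > img[b];
    return a < b;
  });

  DSU dsu(n);
  std::vector<int> comp(n, -1);          // root pixel of the component, -1 = unseen
  std::vector<int> summit(n, -1);        // per root: summit pixel
  std::vector<double> summit_val(n, 0.0);
  std::vector<double> prom(n, -1.0);     // per root: prominence once the comp dies

  double vmin = img[order.back()];

  for (int p : order) {
    const int pr = p % nr, pc = p / nr;
    const double v = img[p];
    int roots[8];
    int nroots = 0;
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + DR[k], cc = pc + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = cc * nr + rr;
      if (comp[q] < 0) continue;
      const int root = dsu.find(comp[q]);
      bool seen = false;
      for (int j = 0; j < nroots; ++j)
        if (roots[j] == root) { seen = true; break; }
      if (!seen) roots[nroots++] = root;
    }
    if (nroots == 0) {
      comp[p] = p;
      summit[p] = p;
      summit_val[p] = v;
    } else {
      int surv = roots[0];
      for (int j = 1; j < nroots; ++j) {
        const int r2 = roots[j];
        const bool better = summit_val[r2] > summit_val[surv] ||
          (summit_val[r2] == summit_val[surv] && summit[r2] < summit[surv]);
        if (better) surv = r2;
      }
      for (int j = 0; j < nroots; ++j) {
        const int r2 = roots[j];
        if (r2 == surv) continue;
        prom[r2] = summit_val[r2] - v;
        dsu.parent[r2] = surv;
      }
      comp[p] = surv;
    }
  }

  // Surviving components: prominence relative to the lowest flooded level.
  std::vector<int> keep;
  for (int p : order) {
    if (comp[p] != p) continue;          // not a component root seed pixel
    if (summit[p] < 0) continue;
    const bool alive = dsu.find(p) == p;
    const double pr_val = alive ? summit_val[p] - vmin : prom[p];
    if (pr_val >= prominence) keep.push_back(p);
  }

  const int m = static_cast<int>(keep.size());
  IntegerVector out_r(m), out_c(m);
  NumericVector out_v(m), out_p(m);
  std::vector<int> visited(n, 0);
  for (int i = 0; i < m; ++i) {
    const int s = summit[keep[i]];
    const double v = img[s];
    // BFS over the 8-connected in-mask plateau of equal value.
    std::vector<int> plateau;
    std::queue<int> q;
    q.push(s);
    visited[s] = i + 1;
    while (!q.empty()) {
      const int p = q.front();
      q.pop();
      plateau.push_back(p);
      const int pr = p % nr, pc = p / nr;
      for (int k = 0; k < 8; ++k) {
        const int rr = pr + DR[k], cc = pc + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int t = cc * nr + rr;
        if (visited[t] == i + 1 || !mask[t] || img[t] != v) continue;
        visited[t] = i + 1;
        q.push(t);
      }
    }
    double mr = 0.0, mc = 0.0;
    for (int p : plateau) { mr += p % nr; mc += p / nr; }
    mr /= plateau.size();
    mc /= plateau.size();
    int best = plateau[0];
    double bestd = R_PosInf;
    for (int p : plateau) {
      const double dr = (p % nr) - mr, dc = (p / nr) - mc;
      const double d = dr * dr + dc * dc;
      if (d < bestd || (d == bestd && p < best)) { bestd = d; best = p; }
    }
    out_r[i] = best % nr + 1;
    out_c[i] = best / nr + 1;
    out_v[i] = v;
    const bool alive = dsu.find(keep[i]) == keep[i];
    out_p[i] = alive ? summit_val[keep[i]] - vmin : prom[keep[i]];
  }
  return List::create(_["row"] = out_r, _["col"] = out_c,
                      _["value"] = out_v, _["prominence"] = out_p);
}

// Meyer-style seeded flooding on an elevation map restricted to a mask.
// Seeds are 1-based (row, col) pairs; the returned grid holds the seed index
// (1..n_seeds) per pixel, 0 for background and inter-region boundary pixels.
// Flooding uses 8-connectivity; ties in elevation are broken first-in
// first-out for determinism.
// [[Rcpp::export(name = ".seeded_watershed_cpp")]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix elev, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  const int nr = elev.nrow(), nc = elev.ncol(), n = nr * nc;
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation and mask dimensions differ");
  const int ns = seeds.nrow();
  std::vector<int> lab(n, 0);            // 0 free, >0 region, -1 boundary

  typedef std::pair<double, std::pair<long long, int> > QItem;
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  long long counter = 0;

  for (int i = 0; i < ns; ++i) {
    const int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside image bounds");
    lab[c * nr + r] = i + 1;
  }
  for (int i = 0; i < ns; ++i) {
    const int r = seeds(i, 0) - 1, c = seeds(i, 1) - 1;
    for (int k = 0; k < 8; ++k) {
      const int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int q = cc * nr + rr;
      if (!mask[q] || lab[q] != 0) continue;
      pq.push(QItem(elev[q], std::make_pair(counter++, q)));
    }
  }

  while (!pq.empty()) {
    const int p = pq.top().second.second;
    pq.pop();
    if (lab[p] != 0) continue;
    const int pr = p % nr, pc = p / nr;
    int found = 0;
    for (int k = 0; k < 8; ++k) {
      const int rr = pr + DR[k], cc = pc + DC[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int lq = lab[cc * nr + rr];
      if (lq > 0) {
        if (found == 0) found = lq;
        else if (found != lq) { found = -1; break; }
      }
    }
    if (found == -1) {
      lab[p] = -1;                        // watershed boundary between regions
    } else if (found > 0) {
      lab[p] = found;
      for (int k = 0; k < 8; ++k) {
        const int rr = pr + DR[k], cc = pc + DC[k];
        if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
        const int q = cc * nr + rr;
        if (mask[q] && lab[q] == 0)
          pq.push(QItem(elev[q], std::make_pair(counter++, q)));
      }
    }
    // found == 0: all labeled neighbors were boundaries; leave unassigned.
  }

  IntegerMatrix out(nr, nc);
  for (int i = 0; i < n; ++i) out[i] = lab[i] > 0 ? lab[i] : 0;
  return out;
}
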