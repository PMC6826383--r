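#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Connected-component labeling and outline measurement for binary masks.
// Conventions: matrices are column-major (R layout); pixel (r, c) 0-based
// occupies the unit square [r, r+1] x [c, c+1] in lattice-vertex space, so
// crack (pixel-edge) vertices carry integer coordinates.

namespace {

struct UF {
  std::vector<int> parent;
  int make() {
    parent.push_back((int)parent.size());
    return (int)parent.size() - 1;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_label(IntegerMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  UF uf;
  uf.make();  // index 0 = background, unused

  std::vector<int> provisional(nr * (size_t)nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      // previously scanned neighbours (column-major: above, and prev column)
      int nb[4];
      int nn = 0;
      if (r > 0 && mask(r - 1, c) != 0) nb[nn++] = provisional[(size_t)c * nr + r - 1];
      if (c > 0) {
        if (mask(r, c - 1) != 0) nb[nn++] = provisional[(size_t)(c - 1) * nr + r];
        if (connectivity == 8) {
          if (r > 0 && mask(r - 1, c - 1) != 0)
            nb[nn++] = provisional[(size_t)(c - 1) * nr + r - 1];
          if (r < nr - 1 && mask(r + 1, c - 1) != 0)
            nb[nn++] = provisional[(size_t)(c - 1) * nr + r + 1];
        }
      }
      int best;
      if (nn == 0) {
        best = uf.make();
      } else {
        best = nb[0];
        for (int k = 1; k < nn; ++k) best = std::min(best, nb[k]);
        for (int k = 0; k < nn; ++k) uf.unite(best, nb[k]);
      }
      provisional[(size_t)c * nr + r] = best;
    }
  }
  // second pass: resolve and relabel consecutively in scan order
  std::vector<int> remap(uf.parent.size(), 0);
  int next_id = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) == 0) continue;
      int root = uf.find(provisional[(size_t)c * nr + r]);
      if (remap[root] == 0) remap[root] = ++next_id;
      lab(r, c) = remap[root];
    }
  }
  return lab;
}

namespace {

// front-left / front-right pixel offsets relative to a vertex, per direction
// directions: 0 = R (0,+1), 1 = D (+1,0), 2 = L (0,-1), 3 = U (-1,0)
const int DR[4] = {0, 1, 0, -1};
const int DC[4] = {1, 0, -1, 0};
const int FL_R[4] = {-1, 0, 0, -1};
const int FL_C[4] = {0, 0, -1, -1};
const int FR_R[4] = {0, 0, -1, -1};
const int FR_C[4] = {0, -1, -1, 0};

inline bool fg(const IntegerMatrix& lab, int r, int c, int id) {
  return r >= 0 && r < lab.nrow() && c >= 0 && c < lab.ncol() && lab(r, c) == id;
}

// Trace the outer crack boundary of component `id`, starting at its
// topmost-leftmost pixel, keeping the component on the right of travel.
// Returns the chain of direction codes.
std::vector<int> trace_outline(const IntegerMatrix& lab, int id, int r0, int c0) {
  std::vector<int> chain;
  int vr = r0, vc = c0, d = 0;  // start at top-left corner vertex, heading right
  const int sr = vr, sc = vc, sd = d;
  const size_t guard = 8 * (size_t)(lab.nrow() + 2) * (lab.ncol() + 2);
  do {
    int nvr = vr + DR[d], nvc = vc + DC[d];
    chain.push_back(d);
    bool lf = fg(lab, nvr + FL_R[d], nvc + FL_C[d], id);
    bool rf = fg(lab, nvr + FR_R[d], nvc + FR_C[d], id);
    if (lf) d = (d + 3) % 4;        // turn left
    else if (!rf) d = (d + 1) % 4;  // turn right
    vr = nvr; vc = nvc;
    if (chain.size() > guard) stop("outline tracing failed to close");
  } while (!(vr == sr && vc == sc && d == sd));
  return chain;
}

double cross(const std::pair<double, double>& o, const std::pair<double, double>& a,
             const std::pair<double, double>& b) {
  return (a.first - o.first) * (b.second - o.second) -
         (a.second - o.second) * (b.first - o.first);
}

// Andrew monotone chain; pts modified (sorted). Returns hull vertices (CCW).
std::vector<std::pair<double, double> > convex_hull(
    std::vector<std::pair<double, double> >& pts) {
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  const size_t n = pts.size();
  if (n < 3) return pts;
  std::vector<std::pair<double, double> > h(2 * n);
  size_t k = 0;
  for (size_t i = 0; i < n; ++i) {
    while (k >= 2 && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  for (size_t i = n - 1, t = k + 1; i-- > 0;) {
    while (k >= t && cross(h[k - 2], h[k - 1], pts[i]) <= 0) --k;
    h[k++] = pts[i];
  }
  h.resize(k - 1);
  return h;
}

}  // namespace

// Measure every labeled component: area, corner-aware outer-boundary
// perimeter, convex hull area of the outer crack polygon, maximum Feret
// diameter, centroid and bounding box (1-based, R convention).
// [[Rcpp::export]]
List cpp_measure(IntegerMatrix lab) {
  const int nr = lab.nrow(), nc = lab.ncol();
  int nlab = 0;
  for (int i = 0; i < nr * nc; ++i) nlab = std::max(nlab, lab[i]);
  if (nlab == 0) {
    return List::create(_["area"] = NumericVector(0), _["perimeter"] = NumericVector(0),
                        _["hull_area"] = NumericVector(0), _["feret"] = NumericVector(0),
                        _["centroid_row"] = NumericVector(0), _["centroid_col"] = NumericVector(0),
                        _["bbox_rmin"] = IntegerVector(0), _["bbox_rmax"] = IntegerVector(0),
                        _["bbox_cmin"] = IntegerVector(0), _["bbox_cmax"] = IntegerVector(0));
  }
  std::vector<double> area(nlab, 0), sum_r(nlab, 0), sum_c(nlab, 0);
  std::vector<int> rmin(nlab, nr), rmax(nlab, -1), cmin(nlab, nc), cmax(nlab, -1);
  std::vector<int> start_r(nlab, -1), start_c(nlab, -1);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int id = lab(r, c);
      if (id == 0) continue;
      int k = id - 1;
      area[k] += 1; sum_r[k] += r; sum_c[k] += c;
      if (r < rmin[k]) rmin[k] = r;
      if (r > rmax[k]) rmax[k] = r;
      if (c < cmin[k]) cmin[k] = c;
      if (c > cmax[k]) cmax[k] = c;
      // topmost, then leftmost pixel: valid start for outer tracing
      if (start_r[k] < 0 || r < start_r[k] || (r == start_r[k] && c < start_c[k])) {
        start_r[k] = r; start_c[k] = c;
      }
    }
  }

  NumericVector perim(nlab), hull_area(nlab), feret(nlab);
  for (int k = 0; k < nlab; ++k) {
    std::vector<int> chain = trace_outline(lab, k + 1, start_r[k], start_c[k]);
    const size_t n = chain.size();
    // rotate so the chain starts immediately after a turn
    size_t rot = 0;
    for (size_t i = 0; i < n; ++i) {
      if (chain[i] != chain[(i + 1) % n]) { rot = (i + 1) % n; break; }
    }
    std::rotate(chain.begin(), chain.begin() + rot, chain.end());
    // run-length encode
    std::vector<int> run_dir, run_len;
    for (size_t i = 0; i < n;) {
      size_t j = i;
      while (j < n && chain[j] == chain[i]) ++j;
      run_dir.push_back(chain[i]);
      run_len.push_back((int)(j - i));
      i = j;
    }
    const int m = (int)run_dir.size();
    // vertex positions along the (rotated) chain, relative to rotated start
    std::vector<std::pair<double, double> > run_start(m), run_end(m);
    {
      double r = 0, c = 0;
      for (int i = 0; i < m; ++i) {
        run_start[i] = std::make_pair(r, c);
        r += DR[run_dir[i]] * (double)run_len[i];
        c += DC[run_dir[i]] * (double)run_len[i];
        run_end[i] = std::make_pair(r, c);
      }
    }
    // corner-aware chord polygon:
    //  - genuine 90-degree corners (both adjacent runs >= 2 px) stay sharp
    //  - staircase runs are represented by their midpoints (per-step chords)
    //  - isolated 1-px risers between two same-direction runs are chorded over
    std::vector<std::pair<double, double> > poly;
    if (m == 1) {
      perim[k] = (double)n;  // cannot happen for a closed curve; guard
    } else {
      for (int i = 0; i < m; ++i) {
        int prev = (i + m - 1) % m, nxt = (i + 1) % m;
        bool genuine_start = std::min(run_len[prev], run_len[i]) >= 2;
        bool genuine_end = std::min(run_len[i], run_len[nxt]) >= 2;
        bool skip = run_len[i] == 1 &&
                    std::max(run_len[prev], run_len[nxt]) >= 2 &&
                    run_dir[prev] == run_dir[nxt];
        if (!(genuine_start && genuine_end) && !skip) {
          poly.push_back(std::make_pair((run_start[i].first + run_end[i].first) / 2,
                                        (run_start[i].second + run_end[i].second) / 2));
        }
        if (genuine_end) poly.push_back(run_end[i]);
      }
      double p = 0;
      const size_t np = poly.size();
      for (size_t i = 0; i < np; ++i) {
        double dr = poly[i].first - poly[(i + 1) % np].first;
        double dc = poly[i].second - poly[(i + 1) % np].second;
        p += std::sqrt(dr * dr + dc * dc);
      }
      perim[k] = p;
    }
    // convex hull of the crack-polygon corner vertices
    std::vector<std::pair<double, double> > corners(run_end.begin(), run_end.end());
    std::vector<std::pair<double, double> > hull = convex_hull(corners);
    double ha = 0, fmax = 0;
    const size_t nh = hull.size();
    for (size_t i = 0; i < nh; ++i) {
      const std::pair<double, double>& a = hull[i];
      const std::pair<double, double>& b = hull[(i + 1) % nh];
      ha += a.first * b.second - b.first * a.second;
      for (size_t j = i + 1; j < nh; ++j) {
        double dr = hull[i].first - hull[j].first;
        double dc = hull[i].second - hull[j].second;
        double dd = dr * dr + dc * dc;
        if (dd > fmax) fmax = dd;
      }
    }
    hull_area[k] = std::fabs(ha) / 2;
    feret[k] = std::sqrt(fmax);
  }

  NumericVector a(nlab), cr(nlab), cc(nlab);
  IntegerVector br1(nlab), br2(nlab), bc1(nlab), bc2(nlab);
  for (int k = 0; k < nlab; ++k) {
    a[k] = area[k];
    cr[k] = sum_r[k] / area[k] + 1;  // 1-based pixel-centre coordinates
    cc[k] = sum_c[k] / area[k] + 1;
    br1[k] = rmin[k] + 1; br2[k] = rmax[k] + 1;
    bc1[k] = cmin[k] + 1; bc2[k] = cmax[k] + 1;
  }
  return List::create(_["area"] = a, _["perimeter"] = perim, _["hull_area"] = hull_area,
                      _["feret"] = feret, _["centroid_row"] = cr, _["centroid_col"] = cc,
                      _["bbox_rmin"] = br1, _["bbox_rmax"] = br2,
                      _["bbox_cmin"] = bc1, _["bbox_cmax"] = bc2);
}
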