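#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// 8-neighbourhood direction codes used in the backlink grid.
// backlink[cell] points FROM the cell TO its predecessor:
// 1=N, 2=NE, 3=E, 4=SE, 5=S, 6=SW, 7=W, 8=NW; 0 = source or unreached.
static const int DROW[9] = {0, -1, -1, 0, 1, 1, 1, 0, -1};
static const int DCOL[9] = {0, 0, 1, 1, 1, 0, -1, -1, -1};
static const double SQRT2 = 1.4142135623730951;

// Accumulated cost-distance from a set of source cells over a resistance
// grid, GIS Cost Distance convention: moving between neighbouring cells
// costs the mean of their resistances times the move length (1 cell
// orthogonal, sqrt(2) diagonal). NA resistance = nodata = impassable.
// Ties in accumulated cost are resolved deterministically: the settle
// queue orders equal costs by flat row-major cell index, and an equal-cost
// relaxation keeps the predecessor with the lower flat index.
// [[Rcpp::export]]
List cost_distance_cpp(NumericMatrix resistance,
                       IntegerVector src_row, IntegerVector src_col) {
  const int nr = resistance.nrow(), nc = resistance.ncol();
  const int n = nr * nc;
  const double INF = std::numeric_limits<double>::infinity();

  std::vector<double> dist(n, INF);
  std::vector<int> back(n, 0);
  // flat index is row-major, 0-based: idx = row * nc + col
  auto flat = [nc](int r, int c) { return r * nc + c; };

  typedef std::pair<double, int> Node;  // (cost, flat index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int k = 0; k < src_row.size(); ++k) {
    int r = src_row[k] - 1, c = src_col[k] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell (%d, %d) is outside the grid", src_row[k], src_col[k]);
    if (NumericMatrix::is_na(resistance(r, c)))
      continue;  // sources on nodata are skipped (validated in R)
    int id = flat(r, c);
    if (dist[id] > 0.0) {
      dist[id] = 0.0;
      pq.push(Node(0.0, id));
    }
  }
  if (pq.empty()) stop("no source cell lies on a valid (non-nodata) cell");

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    const double d = top.first;
    const int id = top.second;
    if (d > dist[id]) continue;  // stale entry
    const int r = id / nc, c = id % nc;
    const double ru = resistance(r, c);
    for (int dir = 1; dir <= 8; ++dir) {
      const int r2 = r + DROW[dir], c2 = c + DCOL[dir];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      const double rv = resistance(r2, c2);
      if (NumericMatrix::is_na(rv)) continue;
      const double len = (DROW[dir] != 0 && DCOL[dir] != 0) ? SQRT2 : 1.0;
      const double nd = d + 0.5 * (ru + rv) * len;
      const int id2 = flat(r2, c2);
      // direction from neighbour back to current = opposite of dir
      const int opp = ((dir + 3) % 8) + 1;
      if (nd < dist[id2]) {
        dist[id2] = nd;
        back[id2] = opp;
        pq.push(Node(nd, id2));
      } else if (nd == dist[id2] && back[id2] != 0) {
        // equal-cost tie: prefer the predecessor with the lower flat index
        const int cur = flat(r2 + DROW[back[id2]], c2 + DCOL[back[id2]]);
        if (id < cur) back[id2] = opp;
      }
    }
  }

  NumericMatrix acc(nr, nc);
  IntegerMatrix bl(nr, nc);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      acc(r, c) = dist[flat(r, c)];
      bl(r, c) = back[flat(r, c)];
    }
  return List::create(_["accumulated"] = acc, _["backlink"] = bl);
}

// For each flagged cell, the class code of the nearest crop cell
// (Euclidean distance between cell centres; ties broken by the lower flat
// row-major index). Searches outward over Chebyshev rings; a ring at
// radius k cannot hold a cell closer than k, so the scan stops once
// k exceeds the best distance found.
// [[Rcpp::export]]
IntegerMatrix nearest_crop_codes_cpp(IntegerMatrix codes, LogicalMatrix is_target,
                                     LogicalMatrix is_crop) {
  const int nr = codes.nrow(), nc = codes.ncol();
  IntegerMatrix out = clone(codes);
  const int kmax = std::max(nr, nc);
  bool any_crop = false;
  for (int r = 0; r < nr && !any_crop; ++r)
    for (int c = 0; c < nc; ++c)
      if (is_crop(r, c)) { any_crop = true; break; }
  if (!any_crop) stop("cannot eliminate margins: the grid has no crop cells");

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!is_target(r, c)) continue;
      double best_d2 = std::numeric_limits<double>::infinity();
      int best_id = -1, best_code = NA_INTEGER;
      for (int k = 1; k <= kmax; ++k) {
        if (static_cast<double>(k) * k > best_d2) break;
        for (int dr = -k; dr <= k; ++dr) {
          const int r2 = r + dr;
          if (r2 < 0 || r2 >= nr) continue;
          const bool edge_row = (dr == -k || dr == k);
          const int step = edge_row ? 1 : 2 * k;
          for (int dc = -k; dc <= k; dc += step) {
            const int c2 = c + dc;
            if (c2 < 0 || c2 >= nc) continue;
            if (!is_crop(r2, c2)) continue;
            const double d2 = static_cast<double>(dr) * dr +
                              static_cast<double>(dc) * dc;
            const int id = r2 * nc + c2;
            if (d2 < best_d2 || (d2 == best_d2 && id < best_id)) {
              best_d2 = d2;
              best_id = id;
              best_code = codes(r2, c2);
            }
          }
        }
      }
      out(r, c) = best_code;
    }
  }
  return out;
}
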