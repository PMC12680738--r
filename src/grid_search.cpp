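// Grid shortest-path search and exact segment/grid crossing tests used by
// the flight-route planner.
//
// The search runs Dijkstra over (cell, incoming-heading) states on an
// 8-connected lattice with unit orthogonal and sqrt(2) diagonal costs,
// minimising (path length, number of turns) lexicographically.  Diagonal
// moves are forbidden when either orthogonally adjacent cell is blocked,
// so optimal paths never cut corners past an obstacle cell.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

struct Node {
  double len;
  int turns;
  int idx;  // r * nc * 9 + c * 9 + heading
  bool operator>(const Node& o) const {
    if (len != o.len) return len > o.len;
    return turns > o.turns;
  }
};

// [[Rcpp::export(name = ".grid_shortest_path")]]
List grid_shortest_path_cpp(LogicalMatrix blocked, int r0, int c0, int r1, int c1) {
  const int nr = blocked.nrow(), nc = blocked.ncol();
  // 1-based from R
  r0--; c0--; r1--; c1--;
  if (r0 < 0 || r0 >= nr || c0 < 0 || c0 >= nc ||
      r1 < 0 || r1 >= nr || c1 < 0 || c1 >= nc)
    stop("start or goal outside grid");
  if (blocked(r0, c0) || blocked(r1, c1))
    stop("start or goal cell is blocked");
  const int H = 9;  // 8 headings + 8 = "no incoming heading"
  const size_t nstate = (size_t)nr * nc * H;
  std::vector<double> dist(nstate, R_PosInf);
  std::vector<int> turns(nstate, INT_MAX);
  std::vector<int> parent(nstate, -1);
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  const double SQ2 = std::sqrt(2.0);
  int s0 = (r0 * nc + c0) * H + 8;
  dist[s0] = 0.0; turns[s0] = 0;
  pq.push({0.0, 0, s0});
  while (!pq.empty()) {
    Node cur = pq.top(); pq.pop();
    if (cur.len > dist[cur.idx] ||
        (cur.len == dist[cur.idx] && cur.turns > turns[cur.idx])) continue;
    int h = cur.idx % H;
    int cell = cur.idx / H;
    int r = cell / nc, c = cell % nc;
    if (r == r1 && c == c1) {
      // reconstruct
      std::vector<int> cells;
      int st = cur.idx;
      while (st >= 0) { cells.push_back(st / H); st = parent[st]; }
      IntegerMatrix path(cells.size(), 2);
      for (size_t i = 0; i < cells.size(); ++i) {
        int cc = cells[cells.size() - 1 - i];
        path(i, 0) = cc / nc + 1;
        path(i, 1) = cc % nc + 1;
      }
      return List::create(_["path"] = path, _["cost"] = cur.len,
                          _["turns"] = cur.turns);
    }
    for (int d = 0; d < 8; ++d) {
      int rr = r + DR[d], cc2 = c + DC[d];
      if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc) continue;
      if (blocked(rr, cc2)) continue;
      bool diag = DR[d] != 0 && DC[d] != 0;
      if (diag && (blocked(r + DR[d], c) || blocked(r, c + DC[d]))) continue;
      double nlen = cur.len + (diag ? SQ2 : 1.0);
      int nturn = cur.turns + ((h != 8 && h != d) ? 1 : 0);
      int nid = ((rr * nc + cc2) * H) + d;
      if (nlen < dist[nid] - 1e-12 ||
          (std::fabs(nlen - dist[nid]) <= 1e-12 && nturn < turns[nid])) {
        dist[nid] = nlen; turns[nid] = nturn; parent[nid] = cur.idx;
        pq.push({nlen, nturn, nid});
      }
    }
  }
  return R_NilValue;  // unreachable
}

// Exact segment vs axis-aligned cell overlap (slab test), conservative at
// boundaries: touching a blocked cell counts as crossing.
static bool seg_aabb(double x1, double y1, double x2, double y2,
                     double xmin, double ymin, double xmax, double ymax) {
  double t0 = 0.0, t1 = 1.0;
  double dx = x2 - x1, dy = y2 - y1;
  const double p[4] = {-dx, dx, -dy, dy};
  const double q[4] = {x1 - xmin, xmax - x1, y1 - ymin, ymax - y1};
  for (int i = 0; i < 4; ++i) {
    if (p[i] == 0.0) {
      if (q[i] < 0.0) return false;
    } else {
      double t = q[i] / p[i];
      if (p[i] < 0.0) { if (t > t1) return false; if (t > t0) t0 = t; }
      else            { if (t < t0) return false; if (t < t1) t1 = t; }
    }
  }
  return t0 <= t1;
}

// [[Rcpp::export(name = ".segment_crosses_blocked")]]
bool segment_crosses_blocked_cpp(LogicalMatrix blocked, double ox, double oy,
                                 double cell, double x1, double y1,
                                 double x2, double y2) {
  const int nr = blocked.nrow(), nc = blocked.ncol();
  const double eps = 1e-9 * cell;
  int i0 = (int)std::floor((std::min(x1, x2) - ox) / cell);
  int i1 = (int)std::floor((std::max(x1, x2) - ox) / cell);
  int j0 = (int)std::floor((std::min(y1, y2) - oy) / cell);
  int j1 = (int)std::floor((std::max(y1, y2) - oy) / cell);
  if (i0 < 0) i0 = 0; if (j0 < 0) j0 = 0;
  if (i1 >= nr) i1 = nr - 1; if (j1 >= nc) j1 = nc - 1;
  for (int i = i0; i <= i1; ++i)
    for (int j = j0; j <= j1; ++j) {
      if (!blocked(i, j)) continue;
      double xmin = ox + i * cell, ymin = oy + j * cell;
      if (seg_aabb(x1, y1, x2, y2, xmin - eps, ymin - eps,
                   xmin + cell + eps, ymin + cell + eps))
        return true;
    }
  return false;
}
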