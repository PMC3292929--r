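#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Transport-mode codes shared with R/AllClasses.R
static const int MODE_NONE = 0;
static const int MODE_WALKING = 1;
static const int MODE_CYCLING = 2;
static const int MODE_MOTORIZED = 3;

static inline double tobler(double slope_deg) {
  return 6.0 * std::exp(-3.5 * std::fabs(std::tan(slope_deg * M_PI / 180.0) + 0.05));
}

struct Node {
  double dist;
  int cell;
  int fac;
  bool operator>(const Node& other) const {
    if (dist != other.dist) return dist > other.dist;
    return fac > other.fac; // deterministic pop order on exact ties
  }
};

// Multi-source least-cost accumulation on the 8-connected cell graph.
// speed: km/h per cell (0 on barriers); mode: transport-mode codes;
// dem: optional elevation (m) for per-edge slope; cellSize: metres.
// fac: k x 2 matrix of 0-based (row, col); facIds: positive ids.
// [[Rcpp::export(name = ".grid_dijkstra")]]
List grid_dijkstra(NumericMatrix speed, IntegerMatrix mode,
                   Nullable<NumericMatrix> dem, double cellSize,
                   IntegerMatrix fac, IntegerVector facIds) {
  const int nr = speed.nrow(), nc = speed.ncol(), n = nr * nc;
  const bool hasDem = dem.isNotNull();
  NumericMatrix z;
  if (hasDem) z = NumericMatrix(dem);

  const double v0 = tobler(0.0);
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> alloc(n, NA_INTEGER);

  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int k = 0; k < fac.nrow(); ++k) {
    int r = fac(k, 0), c = fac(k, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("facility %d lies outside the grid", facIds[k]);
    if (speed(r, c) <= 0.0 || mode(r, c) == MODE_NONE)
      continue; // facility on a barrier cell: cannot seed
    int cell = r + nr * c;
    if (!R_finite(dist[cell]) || facIds[k] < alloc[cell]) {
      dist[cell] = 0.0;
      alloc[cell] = facIds[k];
      pq.push(Node{0.0, cell, facIds[k]});
    }
  }
  if (pq.empty())
    stop("no facility lies on a passable (non-barrier) cell");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    Node nd = pq.top();
    pq.pop();
    if (nd.dist > dist[nd.cell]) continue;
    if (nd.dist == dist[nd.cell] && nd.fac != alloc[nd.cell]) continue;
    int r = nd.cell % nr, c = nd.cell / nr;
    double v1base = speed(r, c);
    int m1 = mode(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double v2base = speed(r2, c2);
      int m2 = mode(r2, c2);
      if (v2base <= 0.0 || m2 == MODE_NONE) continue;
      bool diag = (dr[k] != 0 && dc[k] != 0);
      double d_m = cellSize * (diag ? M_SQRT2 : 1.0);
      double mult = 1.0;
      if (hasDem) {
        double dz = z(r2, c2) - z(r, c);
        double slope = std::atan2(std::fabs(dz), d_m) * 180.0 / M_PI;
        mult = tobler(slope) / v0;
      }
      // slope multiplier applies to human-powered modes only
      double v1 = (m1 == MODE_MOTORIZED) ? v1base : v1base * mult;
      double v2 = (m2 == MODE_MOTORIZED) ? v2base : v2base * mult;
      // half the edge length traversed at each endpoint's effective speed
      double d_km = d_m / 1000.0;
      double w = 60.0 * (d_km / 2.0 / v1 + d_km / 2.0 / v2);
      int cell2 = r2 + nr * c2;
      double cand = nd.dist + w;
      if (cand < dist[cell2] ||
          (cand == dist[cell2] && nd.fac < alloc[cell2])) {
        dist[cell2] = cand;
        alloc[cell2] = nd.fac;
        pq.push(Node{cand, cell2, nd.fac});
      }
    }
  }

  NumericMatrix minutes(nr, nc);
  IntegerMatrix allocation(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      minutes(r, c) = dist[r + nr * c];
      allocation(r, c) = alloc[r + nr * c];
    }
  return List::create(_["minutes"] = minutes, _["allocation"] = allocation);
}
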