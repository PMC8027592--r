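#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dijkstra shortest 3D path length over an 8-connected cell grid.
// Step cost sqrt(planar^2 + dz^2); planar = cell for rook moves,
// cell*sqrt(2) for diagonal moves. Sources (0-based row/col) cost 0.
// [[Rcpp::export]]
NumericMatrix grid_path_distance(NumericMatrix elev, IntegerMatrix sources,
                                 double cell_size) {
  const int nr = elev.nrow(), nc = elev.ncol();
  NumericMatrix dist(nr, nc);
  std::fill(dist.begin(), dist.end(), R_PosInf);

  typedef std::pair<double, int> Node;  // (distance, flat index row*nc+col)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int i = 0; i < sources.nrow(); ++i) {
    int r = sources(i, 0), c = sources(i, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside grid");
    dist(r, c) = 0.0;
    pq.push(Node(0.0, r * nc + c));
  }

  static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double diag = cell_size * M_SQRT2;

  while (!pq.empty()) {
    double d = pq.top().first;
    int idx = pq.top().second;
    pq.pop();
    int r = idx / nc, c = idx % nc;
    if (d > dist(r, c)) continue;
    double z0 = elev(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double planar = (dr[k] != 0 && dc[k] != 0) ? diag : cell_size;
      double dz = elev(r2, c2) - z0;
      double nd = d + std::sqrt(planar * planar + dz * dz);
      if (nd < dist(r2, c2)) {
        dist(r2, c2) = nd;
        pq.push(Node(nd, r2 * nc + c2));
      }
    }
  }
  return dist;
}
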