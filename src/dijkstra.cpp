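#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Multi-source Dijkstra on an 8-connected grid of per-cell crossing times.
//
// cost(i, j): seconds to cross cell (i, j); NA = untraversable.
// The step cost between adjacent cells a and b is 0.5 * (c_a + c_b) * d,
// with d = 1 for orthogonal moves and sqrt(2) for diagonal moves (distances
// in cell units), so a straight orthogonal traverse of k uniform cells
// costs exactly k * c.
//
// Returns accumulated seconds to the nearest source; R_PosInf where no
// path exists; NA where the surface itself is NA.
// [[Rcpp::export]]
NumericMatrix grid_dijkstra(NumericMatrix cost,
                            IntegerVector source_rows,
                            IntegerVector source_cols) {
  const int nr = cost.nrow(), nc = cost.ncol();
  const int n = nr * nc;
  if (source_rows.size() == 0)
    stop("at least one source cell is required");

  std::vector<double> dist(n, R_PosInf);
  std::vector<bool> done(n, false);

  typedef std::pair<double, int> Node;  // (distance, flat index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int k = 0; k < source_rows.size(); ++k) {
    int r = source_rows[k] - 1, c = source_cols[k] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside the grid");
    if (NumericMatrix::is_na(cost(r, c)))
      stop("source cell lies on an impassable (NA) cell");
    int idx = r + c * nr;
    dist[idx] = 0.0;
    pq.push(Node(0.0, idx));
  }

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    int ur = u % nr, uc = u / nr;
    double cu = cost(ur, uc);

    for (int k = 0; k < 8; ++k) {
      int vr = ur + dr[k], vc = uc + dc[k];
      if (vr < 0 || vr >= nr || vc < 0 || vc >= nc) continue;
      double cv = cost(vr, vc);
      if (NumericMatrix::is_na(cv)) continue;
      int v = vr + vc * nr;
      if (done[v]) continue;
      double step = 0.5 * (cu + cv) * ((dr[k] != 0 && dc[k] != 0) ? sqrt2 : 1.0);
      double nd = top.first + step;
      if (nd < dist[v]) {
        dist[v] = nd;
        pq.push(Node(nd, v));
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (NumericMatrix::is_na(cost(r, c)))
        out(r, c) = NA_REAL;
      else
        out(r, c) = dist[r + c * nr];
    }
  return out;
}
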