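// Grid-graph utilities: Dijkstra geodesic distances on the conductive node
// graph (8-neighbour, Euclidean edge weights) and connected-component
// labelling of boolean node masks (8-connectivity).

#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Edges are gated by the elements they touch: an axis-aligned edge is
// passable iff at least one of its two flanking elements is conductive; a
// diagonal edge iff the single element it crosses is conductive. This
// makes one-element-thick nonconductive walls block the path graph just
// as they block diffusion.
// [[Rcpp::export(name = ".grid_dijkstra_cpp")]]
NumericVector grid_dijkstra_cpp(int nx, int ny, double h,
                                LogicalVector elem_cond, int src) {
  const int nn = nx * ny;
  const int enx = nx - 1;
  const int eny = (ny > 1) ? ny - 1 : 1;
  if ((int)elem_cond.size() != enx * eny) stop("element mask has wrong length");
  if (src < 0 || src >= nn) stop("source out of range");

  // element conductivity lookup with bounds clipping to "not conductive"
  #define ECOND(ei, ej) ((ei) >= 0 && (ei) < enx && (ej) >= 0 && \
                         (ej) < eny && elem_cond[(ej) * enx + (ei)])

  NumericVector dist(nn, R_PosInf);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  const double hd = h * std::sqrt(2.0);

  while (!pq.empty()) {
    const QE top = pq.top(); pq.pop();
    const double d = top.first;
    const int n = top.second;
    if (d > dist[n]) continue;
    const int i = n % nx, j = n / nx;
    for (int k = 0; k < 8; ++k) {
      static const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
      static const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
      const int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
      bool open;
      if (ny == 1) {
        if (dj[k] != 0) continue;
        open = ECOND(di[k] < 0 ? i - 1 : i, 0);
      } else if (dj[k] == 0) {          // x edge
        const int ei = (di[k] < 0) ? i - 1 : i;
        open = ECOND(ei, j - 1) || ECOND(ei, j);
      } else if (di[k] == 0) {          // y edge
        const int ej = (dj[k] < 0) ? j - 1 : j;
        open = ECOND(i - 1, ej) || ECOND(i, ej);
      } else {                          // diagonal: single crossed element
        const int ei = (di[k] < 0) ? i - 1 : i;
        const int ej = (dj[k] < 0) ? j - 1 : j;
        open = ECOND(ei, ej);
      }
      if (!open) continue;
      const int m = jj * nx + ii;
      const double w = (dj[k] == 0 || di[k] == 0) ? h : hd;
      if (d + w < dist[m]) {
        dist[m] = d + w;
        pq.push(QE(dist[m], m));
      }
    }
  }
  #undef ECOND
  return dist;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, int nx, int ny) {
  const int nn = nx * ny;
  if ((int)mask.size() != nn) stop("mask has wrong length");
  IntegerVector lab(nn, 0);
  int next = 0;
  std::vector<int> stack;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  for (int n0 = 0; n0 < nn; ++n0) {
    if (!mask[n0] || lab[n0] != 0) continue;
    lab[n0] = ++next;
    stack.push_back(n0);
    while (!stack.empty()) {
      const int n = stack.back(); stack.pop_back();
      const int i = n % nx, j = n / nx;
      for (int k = 0; k < 8; ++k) {
        const int ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny) continue;
        const int m = jj * nx + ii;
        if (mask[m] && lab[m] == 0) {
          lab[m] = next;
          stack.push_back(m);
        }
      }
    }
  }
  return lab;
}
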