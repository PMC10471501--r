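#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Union-find with path compression + union by size.
static int uf_find(std::vector<int>& parent, int x) {
  int root = x;
  while (parent[root] != root) root = parent[root];
  while (parent[x] != root) { int nxt = parent[x]; parent[x] = root; x = nxt; }
  return root;
}

// Threshold-free cluster enhancement on an arbitrary undirected graph.
//
// stat:    node statistic (only the positive part is enhanced)
// adj_i/j: 0-based edge list (each undirected edge once)
// dh:      height step; thresholds are dh, 2*dh, ... up to max(stat)
// E, H:    extent and height exponents
//
// For node g, TFCE(g) = sum over thresholds h <= stat[g] of
//   dh * extent(h, g)^E * h^H,
// where extent(h, g) is the size of the connected component of
// {v : stat[v] >= h} containing g. Nodes are activated in descending
// threshold order and merged with a union-find; per threshold every
// active node accumulates its component's contribution.
// [[Rcpp::export(name = ".tfce_graph")]]
NumericVector tfce_graph(NumericVector stat, IntegerVector adj_i,
                         IntegerVector adj_j, double dh, double E, double H) {
  const int n = stat.size();
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (int i = 0; i < n; ++i) if (stat[i] > mx) mx = stat[i];
  if (mx <= 0.0 || dh <= 0.0) return out;

  const int nlev = (int) std::floor(mx / dh + 1e-9);
  if (nlev < 1) return out;

  // adjacency in CSR form
  std::vector<int> deg(n, 0);
  const int m = adj_i.size();
  for (int e = 0; e < m; ++e) { deg[adj_i[e]]++; deg[adj_j[e]]++; }
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> nbr(off[n]);
  std::vector<int> cur(off.begin(), off.end() - 1);
  for (int e = 0; e < m; ++e) {
    nbr[cur[adj_i[e]]++] = adj_j[e];
    nbr[cur[adj_j[e]]++] = adj_i[e];
  }

  // nodes sorted by stat descending
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return stat[a] > stat[b]; });

  std::vector<int> parent(n), csize(n, 0);
  std::vector<char> active(n, 0);
  for (int i = 0; i < n; ++i) parent[i] = i;

  std::vector<int> active_nodes;
  active_nodes.reserve(n);

  int next = 0; // next node in descending order to activate
  for (int lev = nlev; lev >= 1; --lev) {
    const double h = lev * dh;
    while (next < n && stat[order[next]] >= h - 1e-12) {
      int v = order[next++];
      active[v] = 1; csize[v] = 1;
      active_nodes.push_back(v);
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int w = nbr[k];
        if (!active[w]) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          if (csize[rv] < csize[rw]) std::swap(rv, rw);
          parent[rw] = rv;
          csize[rv] += csize[rw];
        }
      }
    }
    const double hH = std::pow(h, H);
    for (size_t a = 0; a < active_nodes.size(); ++a) {
      int v = active_nodes[a];
      int r = uf_find(parent, v);
      out[v] += dh * std::pow((double) csize[r], E) * hH;
    }
  }
  return out;
}
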