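#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// For each query vertex, the set of mesh vertices whose graph-geodesic
// distance (shortest path along edges, edge weights = Euclidean lengths)
// is at most `radius`. Truncated Dijkstra per query. Vertices/edges 1-based.
// [[Rcpp::export]]
List mesh_geodesic_balls_cpp(int n_vertices, IntegerMatrix edges,
                             NumericVector lengths, IntegerVector queries,
                             double radius) {
  // CSR adjacency
  std::vector<int> deg(n_vertices, 0);
  int ne = edges.nrow();
  for (int e = 0; e < ne; ++e) {
    deg[edges(e, 0) - 1]++;
    deg[edges(e, 1) - 1]++;
  }
  std::vector<int> off(n_vertices + 1, 0);
  for (int v = 0; v < n_vertices; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(off[n_vertices]);
  std::vector<double> w(off[n_vertices]);
  std::vector<int> fill(n_vertices, 0);
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[off[a] + fill[a]] = b; w[off[a] + fill[a]] = lengths[e]; fill[a]++;
    adj[off[b] + fill[b]] = a; w[off[b] + fill[b]] = lengths[e]; fill[b]++;
  }

  std::vector<double> dist(n_vertices, -1.0);
  std::vector<int> touched;
  typedef std::pair<double, int> QE;

  List out(queries.size());
  for (int qi = 0; qi < queries.size(); ++qi) {
    int src = queries[qi] - 1;
    std::priority_queue<QE, std::vector<QE>, std::greater<QE> > heap;
    dist[src] = 0.0;
    touched.push_back(src);
    heap.push(QE(0.0, src));
    std::vector<int> members;
    while (!heap.empty()) {
      QE top = heap.top();
      heap.pop();
      int v = top.second;
      if (top.first > dist[v] + 1e-12) continue;
      members.push_back(v + 1);
      for (int t = off[v]; t < off[v + 1]; ++t) {
        int nb = adj[t];
        double nd = top.first + w[t];
        if (nd <= radius && (dist[nb] < 0 || nd < dist[nb])) {
          dist[nb] = nd;
          touched.push_back(nb);
          heap.push(QE(nd, nb));
        }
      }
    }
    out[qi] = IntegerVector(members.begin(), members.end());
    for (size_t t = 0; t < touched.size(); ++t) dist[touched[t]] = -1.0;
    touched.clear();
  }
  return out;
}
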