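#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>

// Successive-shortest-path min-cost max-flow with Dijkstra + node
// potentials (Johnson reweighting). Edge costs must be non-negative on the
// initial graph; residual negative costs are absorbed by the potentials.
// Used by the size-constrained k-means assignment step, where the
// transportation problem is small (hundreds of nodes, tens of thousands of
// arcs) but must be solved exactly.

namespace {

struct Edge {
  int to;
  int cap;
  double cost;
  int rev;  // index of reverse edge in graph[to]
};

}  // namespace

// [[Rcpp::export(name = ".mcf_solve")]]
Rcpp::List mcf_solve(int n_nodes, Rcpp::IntegerVector from, Rcpp::IntegerVector to,
                     Rcpp::IntegerVector cap, Rcpp::NumericVector cost,
                     int source, int sink) {
  const int m = from.size();
  std::vector<std::vector<Edge> > g(n_nodes);
  std::vector<std::pair<int, int> > loc(m);  // original edge -> (node, idx)
  for (int e = 0; e < m; ++e) {
    int u = from[e], v = to[e];
    if (u < 0 || u >= n_nodes || v < 0 || v >= n_nodes)
      Rcpp::stop("edge endpoint out of range");
    if (cost[e] < 0) Rcpp::stop("initial edge costs must be non-negative");
    Edge fwd = {v, cap[e], cost[e], (int)g[v].size()};
    Edge bwd = {u, 0, -cost[e], (int)g[u].size()};
    loc[e] = std::make_pair(u, (int)g[u].size());
    g[u].push_back(fwd);
    g[v].push_back(bwd);
  }

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> pot(n_nodes, 0.0), dist(n_nodes);
  std::vector<int> prev_node(n_nodes), prev_edge(n_nodes);
  long long total_flow = 0;
  long double total_cost = 0.0;

  typedef std::pair<double, int> QItem;
  while (true) {
    std::fill(dist.begin(), dist.end(), INF);
    dist[source] = 0.0;
    std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
    pq.push(std::make_pair(0.0, source));
    while (!pq.empty()) {
      QItem top = pq.top();
      pq.pop();
      int u = top.second;
      if (top.first > dist[u] + 1e-12) continue;
      for (size_t i = 0; i < g[u].size(); ++i) {
        const Edge &e = g[u][i];
        if (e.cap <= 0) continue;
        double nd = dist[u] + e.cost + pot[u] - pot[e.to];
        if (nd < dist[e.to] - 1e-12) {
          dist[e.to] = nd;
          prev_node[e.to] = u;
          prev_edge[e.to] = (int)i;
          pq.push(std::make_pair(nd, e.to));
        }
      }
    }
    if (dist[sink] == INF) break;
    for (int v = 0; v < n_nodes; ++v)
      if (dist[v] < INF) pot[v] += dist[v];

    int push = std::numeric_limits<int>::max();
    for (int v = sink; v != source; v = prev_node[v])
      push = std::min(push, g[prev_node[v]][prev_edge[v]].cap);
    for (int v = sink; v != source; v = prev_node[v]) {
      Edge &e = g[prev_node[v]][prev_edge[v]];
      e.cap -= push;
      g[v][e.rev].cap += push;
      total_cost += (long double)e.cost * push;
    }
    total_flow += push;
  }

  Rcpp::IntegerVector flow(m);
  for (int e = 0; e < m; ++e) {
    const Edge &fwd = g[loc[e].first][loc[e].second];
    flow[e] = cap[e] - fwd.cap;
  }
  return Rcpp::List::create(Rcpp::Named("flow") = flow,
                            Rcpp::Named("max_flow") = (double)total_flow,
                            Rcpp::Named("cost") = (double)total_cost);
}
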