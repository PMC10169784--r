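#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact earth mover's distance between two weighted point sets with equal
// total mass, solved as a transportation problem by successive shortest
// augmenting paths with node potentials (costs stay non-negative, so plain
// Dijkstra applies throughout).  Sizes here are a few hundred bins per side.
//
// Returns the optimal total transport cost (= EMD when total mass is 1).
// [[Rcpp::export]]
double cpp_emd(NumericVector wa, NumericVector wb, NumericMatrix cost) {
  int na = wa.size(), nb = wb.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> supply(wa.begin(), wa.end());
  std::vector<double> demand(wb.begin(), wb.end());
  std::vector<std::vector<double>> flow(na, std::vector<double>(nb, 0.0));
  // potentials: u for supply nodes, v for demand nodes
  std::vector<double> u(na, 0.0), v(nb, 0.0);
  double total = 0.0;
  const double EPS = 1e-12;

  while (true) {
    // remaining mass?
    double rem = 0.0;
    for (int i = 0; i < na; ++i) rem += supply[i];
    if (rem <= EPS) break;

    // Dijkstra on the bipartite residual graph from all supply-positive
    // sources.  Node ids: 0..na-1 supply, na..na+nb-1 demand.
    int N = na + nb;
    std::vector<double> dist(N, INF);
    std::vector<int> prev(N, -1);
    std::vector<bool> done(N, false);
    for (int i = 0; i < na; ++i)
      if (supply[i] > EPS) dist[i] = 0.0;
    while (true) {
      int best = -1;
      double bd = INF;
      for (int i = 0; i < N; ++i)
        if (!done[i] && dist[i] < bd) { bd = dist[i]; best = i; }
      if (best < 0) break;
      done[best] = true;
      if (best < na) {
        int i = best;
        for (int j = 0; j < nb; ++j) {
          double rc = cost(i, j) - u[i] - v[j];  // reduced cost >= 0
          if (rc < 0) rc = 0;                    // guard rounding
          if (dist[i] + rc < dist[na + j] - 1e-18) {
            dist[na + j] = dist[i] + rc;
            prev[na + j] = i;
          }
        }
      } else {
        int j = best - na;
        for (int i = 0; i < na; ++i) {
          if (flow[i][j] <= EPS) continue;       // backward arc needs flow
          double rc = -(cost(i, j) - u[i] - v[j]);
          if (rc < 0) rc = 0;
          if (dist[na + j] + rc < dist[i] - 1e-18) {
            dist[i] = dist[na + j] + rc;
            prev[i] = na + j;
          }
        }
      }
    }
    // pick reachable demand node with residual demand and minimal distance
    int tgt = -1;
    double bd = INF;
    for (int j = 0; j < nb; ++j)
      if (demand[j] > EPS && dist[na + j] < bd) { bd = dist[na + j]; tgt = j; }
    if (tgt < 0) stop("transport network disconnected (mass mismatch?)");

    // bottleneck along the path
    double push = demand[tgt];
    int node = na + tgt;
    while (prev[node] != -1) {
      int p = prev[node];
      if (node >= na) {
        // forward arc p -> node: unlimited capacity
      } else {
        // backward arc (demand p-na) -> supply node: capacity = flow
        push = std::min(push, flow[node][p - na]);
      }
      node = p;
    }
    push = std::min(push, supply[node]);

    // apply
    node = na + tgt;
    while (prev[node] != -1) {
      int p = prev[node];
      if (node >= na) flow[p][node - na] += push;
      else flow[node][p - na] -= push;
      node = p;
    }
    supply[node] -= push;
    demand[tgt] -= push;

    // update potentials (capped at the target distance, Johnson-style)
    for (int i = 0; i < na; ++i)
      u[i] -= std::min(dist[i], bd);
    for (int j = 0; j < nb; ++j)
      v[j] += std::min(dist[na + j], bd);
  }

  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) total += flow[i][j] * cost(i, j);
  return total;
}
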