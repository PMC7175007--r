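#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Adjacency lists from a dense 0/1 matrix
static std::vector<std::vector<int>> adj_list(const IntegerMatrix &A) {
  int n = A.nrow();
  std::vector<std::vector<int>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// All-pairs geodesic distances by BFS; unreachable pairs get NA.
// [[Rcpp::export]]
IntegerMatrix bfs_distances_cpp(IntegerMatrix A) {
  int n = A.nrow();
  auto adj = adj_list(A);
  IntegerMatrix D(n, n);
  std::fill(D.begin(), D.end(), NA_INTEGER);
  std::vector<int> dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      for (int w : adj[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
      }
    }
    for (int t = 0; t < n; ++t)
      if (dist[t] >= 0) D(s, t) = dist[t];
  }
  return D;
}

// Brandes betweenness with fractional credit for tied geodesics,
// unnormalised; undirected graphs (accumulation halved).
// [[Rcpp::export]]
NumericVector brandes_betweenness_cpp(IntegerMatrix A) {
  int n = A.nrow();
  auto adj = adj_list(A);
  NumericVector bc(n, 0.0);
  std::vector<int> dist(n), stack_order;
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  stack_order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (auto &p : pred) p.clear();
    stack_order.clear();
    dist[s] = 0; sigma[s] = 1.0;
    std::queue<int> q;
    q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      stack_order.push_back(v);
      for (int w : adj[v]) {
        if (dist[w] < 0) { dist[w] = dist[v] + 1; q.push(w); }
        if (dist[w] == dist[v] + 1) { sigma[w] += sigma[v]; pred[w].push_back(v); }
      }
    }
    for (int i = (int)stack_order.size() - 1; i >= 0; --i) {
      int w = stack_order[i];
      for (int v : pred[w])
        delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }
  return bc / 2.0;  // each unordered pair counted from both endpoints
}
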