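// Core of the shortest-path Steiner tree heuristic.
//
// The ensemble discovery runs this routine hundreds of times per dataset,
// so the whole inner loop (Dijkstra distances, forest merging, MST,
// non-terminal leaf pruning) lives here. Vertices are 0-based integer ids;
// the R wrapper passes ids in lexicographic name order, so "smallest id"
// tie-breaks are lexicographic name tie-breaks.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

struct Adj {
  // CSR-style adjacency for an undirected graph
  std::vector<int> head, nxt, to;
  std::vector<double> w;
  explicit Adj(int n, const IntegerVector& ei, const IntegerVector& ej,
               const NumericVector& ew)
      : head(n, -1) {
    int m = ei.size();
    nxt.reserve(2 * m); to.reserve(2 * m); w.reserve(2 * m);
    for (int e = 0; e < m; ++e) {
      to.push_back(ej[e]); w.push_back(ew[e]);
      nxt.push_back(head[ei[e]]); head[ei[e]] = (int)to.size() - 1;
      to.push_back(ei[e]); w.push_back(ew[e]);
      nxt.push_back(head[ej[e]]); head[ej[e]] = (int)to.size() - 1;
    }
  }
};

static void dijkstra(const Adj& adj, int src, std::vector<double>& dist,
                     std::vector<int>& pred) {
  int n = adj.head.size();
  dist.assign(n, INF);
  pred.assign(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[src] = 0.0;
  pq.push(QE(0.0, src));
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    for (int e = adj.head[u]; e != -1; e = adj.nxt[e]) {
      int v = adj.to[e];
      double nd = dist[u] + adj.w[e];
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u;
        pq.push(QE(nd, v));
      }
    }
  }
}

struct DSU {
  std::vector<int> p;
  explicit DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    p[b] = a;
    return true;
  }
};

// [[Rcpp::export(name = ".steiner_sph_cpp")]]
List steiner_sph_cpp(int n, IntegerVector ei, IntegerVector ej,
                     NumericVector ew, IntegerVector terminals) {
  Adj adj(n, ei, ej, ew);
  int nt = terminals.size();

  // forest state: member vertices, their Dijkstra rows, component labels
  std::vector<int> tv;                       // forest vertex ids
  std::vector<int> pos(n, -1);               // vertex id -> index in tv
  std::vector<std::vector<double> > drow;    // full distance row per member
  std::vector<std::vector<int> > prow;       // predecessor row per member
  std::vector<int> comp;                     // component label per member

  tv.reserve(4 * nt);
  for (int i = 0; i < nt; ++i) {
    int t = terminals[i];
    if (pos[t] != -1) continue;              // duplicated terminal
    pos[t] = (int)tv.size();
    tv.push_back(t);
    comp.push_back((int)comp.size());
    drow.push_back(std::vector<double>());
    prow.push_back(std::vector<int>());
    dijkstra(adj, t, drow.back(), prow.back());
  }
  int ncomp = (int)tv.size();

  while (ncomp > 1) {
    // closest pair of forest vertices in different components;
    // ties broken by smallest (unordered) id pair
    double best = INF;
    int bi = -1, bj = -1;
    int k = (int)tv.size();
    for (int i = 0; i < k; ++i) {
      const std::vector<double>& di = drow[i];
      for (int j = i + 1; j < k; ++j) {
        if (comp[i] == comp[j]) continue;
        double d = di[tv[j]];
        if (d > best) continue;
        if (d < best) { best = d; bi = i; bj = j; continue; }
        int a1 = std::min(tv[i], tv[j]), b1 = std::max(tv[i], tv[j]);
        int a0 = std::min(tv[bi], tv[bj]), b0 = std::max(tv[bi], tv[bj]);
        if (a1 < a0 || (a1 == a0 && b1 < b0)) { bi = i; bj = j; }
      }
    }
    if (bi < 0 || !(best < INF))
      stop("terminals are not connected in the network");

    // walk the shortest path from tv[bj] back to tv[bi]
    std::vector<int> path;
    for (int x = tv[bj]; x != -1; x = prow[bi][x]) path.push_back(x);

    // merge every component the path touches, then add the new vertices
    int newc = comp[bi];
    for (size_t s = 0; s < path.size(); ++s) {
      int x = path[s];
      if (pos[x] == -1) continue;
      int oc = comp[pos[x]];
      if (oc == newc) continue;
      for (size_t q = 0; q < comp.size(); ++q)
        if (comp[q] == oc) comp[q] = newc;
      --ncomp;
    }
    for (size_t s = 0; s < path.size(); ++s) {
      int x = path[s];
      if (pos[x] != -1) continue;
      pos[x] = (int)tv.size();
      tv.push_back(x);
      comp.push_back(newc);
      drow.push_back(std::vector<double>());
      prow.push_back(std::vector<int>());
      dijkstra(adj, x, drow.back(), prow.back());
    }
  }

  // MST (Kruskal) of the subgraph induced by the forest vertices;
  // ties broken by smallest id pair
  int m = ei.size();
  std::vector<int> cand;
  cand.reserve(m);
  for (int e = 0; e < m; ++e)
    if (pos[ei[e]] != -1 && pos[ej[e]] != -1) cand.push_back(e);
  std::vector<int> order(cand);
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (ew[a] != ew[b]) return ew[a] < ew[b];
    int a0 = std::min(ei[a], ej[a]), a1 = std::max(ei[a], ej[a]);
    int b0 = std::min(ei[b], ej[b]), b1 = std::max(ei[b], ej[b]);
    return a0 != b0 ? a0 < b0 : a1 < b1;
  });
  int k = (int)tv.size();
  DSU dsu(k);
  std::vector<int> tree_edges;
  tree_edges.reserve(k - 1);
  for (size_t s = 0; s < order.size(); ++s) {
    int e = order[s];
    if (dsu.unite(pos[ei[e]], pos[ej[e]])) tree_edges.push_back(e);
  }
  if ((int)tree_edges.size() != k - 1)
    stop("internal error: induced subgraph of the forest is disconnected");

  // iteratively prune non-terminal leaves
  std::vector<bool> isterm(n, false);
  for (int i = 0; i < nt; ++i) isterm[terminals[i]] = true;
  std::vector<int> deg(n, 0);
  std::vector<std::vector<std::pair<int, int> > > tadj(n);
  for (size_t s = 0; s < tree_edges.size(); ++s) {
    int e = tree_edges[s];
    ++deg[ei[e]]; ++deg[ej[e]];
    tadj[ei[e]].push_back(std::make_pair(ej[e], e));
    tadj[ej[e]].push_back(std::make_pair(ei[e], e));
  }
  std::vector<bool> vkeep(n, false), ekeep(m, false);
  for (int i = 0; i < k; ++i) vkeep[tv[i]] = true;
  for (size_t s = 0; s < tree_edges.size(); ++s) ekeep[tree_edges[s]] = true;
  std::queue<int> leaves;
  for (int i = 0; i < k; ++i)
    if (deg[tv[i]] <= 1 && !isterm[tv[i]]) leaves.push(tv[i]);
  while (!leaves.empty()) {
    int u = leaves.front(); leaves.pop();
    if (!vkeep[u] || deg[u] > 1) continue;
    vkeep[u] = false;
    for (size_t s = 0; s < tadj[u].size(); ++s) {
      int v = tadj[u][s].first, e = tadj[u][s].second;
      if (!ekeep[e]) continue;
      ekeep[e] = false;
      --deg[u]; --deg[v];
      if (vkeep[v] && deg[v] <= 1 && !isterm[v]) leaves.push(v);
    }
  }

  std::vector<int> vout;
  for (int i = 0; i < k; ++i)
    if (vkeep[tv[i]]) vout.push_back(tv[i]);
  std::sort(vout.begin(), vout.end());
  std::vector<int> e1, e2;
  double total = 0.0;
  for (size_t s = 0; s < tree_edges.size(); ++s) {
    int e = tree_edges[s];
    if (!ekeep[e]) continue;
    e1.push_back(ei[e]); e2.push_back(ej[e]);
    total += ew[e];
  }
  return List::create(_["vertices"] = wrap(vout),
                      _["edge_i"] = wrap(e1),
                      _["edge_j"] = wrap(e2),
                      _["total_weight"] = total);
}
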