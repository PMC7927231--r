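// Graph core for structural covariance networks.
//
// All routines operate on dense symmetric matrices (68 or 19 nodes in the
// intended use), so O(n^2)/O(n*m) algorithms with contiguous storage beat
// sparse representations.  Louvain uses its own mt19937 stream so results
// are reproducible from an integer seed independently of R's RNG state.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <map>
#include <queue>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct UnionFind {
  std::vector<int> parent, rank_;
  explicit UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  bool unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

struct Edge {
  double w;
  int i, j;
};

// Sort key: decreasing weight, ties by lexicographic (i, j) for
// bit-reproducibility.
inline bool edge_before(const Edge& a, const Edge& b) {
  if (a.w != b.w) return a.w > b.w;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

// Inclusion order for density thresholding: maximum-spanning-tree backbone
// first (guarantees connectedness), then remaining candidate edges by
// decreasing weight.  In "positive" ranking mode non-positive correlations
// are not candidates beyond the backbone; in "absolute" mode edges are
// ranked by |w|.
void build_edge_order(const NumericMatrix& R, bool absolute_rank,
                      std::vector<int>& oi, std::vector<int>& oj,
                      int& n_mst) {
  const int n = R.nrow();
  std::vector<Edge> edges;
  edges.reserve(static_cast<size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double w = R(i, j);
      edges.push_back({absolute_rank ? std::fabs(w) : w, i, j});
    }
  std::stable_sort(edges.begin(), edges.end(), edge_before);

  const size_t M = edges.size();
  std::vector<char> used(M, 0);
  UnionFind uf(n);
  oi.clear();
  oj.clear();
  n_mst = 0;
  for (size_t k = 0; k < M && n_mst < n - 1; ++k) {
    if (uf.unite(edges[k].i, edges[k].j)) {
      oi.push_back(edges[k].i);
      oj.push_back(edges[k].j);
      used[k] = 1;
      ++n_mst;
    }
  }
  for (size_t k = 0; k < M; ++k) {
    if (used[k]) continue;
    if (!absolute_rank && edges[k].w <= 0.0) continue;
    oi.push_back(edges[k].i);
    oj.push_back(edges[k].j);
  }
}

typedef std::vector<std::vector<int> > AdjList;

AdjList adj_from_matrix(const IntegerMatrix& A) {
  const int n = A.nrow();
  AdjList adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) adj[i].push_back(j);
  return adj;
}

// --- scalar metrics on an adjacency list -------------------------------

void triangle_counts(const AdjList& adj, std::vector<double>& tri,
                     std::vector<int>& deg) {
  const int n = static_cast<int>(adj.size());
  tri.assign(n, 0.0);
  deg.assign(n, 0);
  std::vector<char> is_nb(n, 0);
  for (int v = 0; v < n; ++v) deg[v] = static_cast<int>(adj[v].size());
  for (int v = 0; v < n; ++v) {
    for (int u : adj[v]) is_nb[u] = 1;
    for (int u : adj[v]) {
      if (u < v) continue;
      for (int w : adj[u])
        if (w > u && is_nb[w]) {
          tri[v] += 1.0;
          tri[u] += 1.0;
          tri[w] += 1.0;
        }
    }
    for (int u : adj[v]) is_nb[u] = 0;
  }
}

double transitivity_adj(const AdjList& adj) {
  std::vector<double> tri;
  std::vector<int> deg;
  triangle_counts(adj, tri, deg);
  double num = 0.0, den = 0.0;
  for (size_t v = 0; v < adj.size(); ++v) {
    num += 2.0 * tri[v];
    den += static_cast<double>(deg[v]) * (deg[v] - 1);
  }
  return den > 0.0 ? num / den : 0.0;
}

void clustering_adj(const AdjList& adj, std::vector<double>& per_node) {
  std::vector<double> tri;
  std::vector<int> deg;
  triangle_counts(adj, tri, deg);
  per_node.assign(adj.size(), 0.0);
  for (size_t v = 0; v < adj.size(); ++v)
    if (deg[v] >= 2)
      per_node[v] = 2.0 * tri[v] /
                    (static_cast<double>(deg[v]) * (deg[v] - 1));
}

// Pearson correlation of degrees over the 2m ordered edge endpoints.
double assortativity_adj(const AdjList& adj) {
  double sx = 0.0, sxx = 0.0, sxy = 0.0;
  double n2m = 0.0;
  const int n = static_cast<int>(adj.size());
  for (int v = 0; v < n; ++v) {
    double kv = static_cast<double>(adj[v].size());
    for (int u : adj[v]) {
      double ku = static_cast<double>(adj[u].size());
      sx += kv;
      sxx += kv * kv;
      sxy += kv * ku;
      n2m += 1.0;
    }
  }
  if (n2m < 2.0) return NA_REAL;
  double mean = sx / n2m;
  double var = sxx / n2m - mean * mean;
  double cov = sxy / n2m - mean * mean;
  if (var <= 1e-14) return NA_REAL;  // regular graph: undefined
  return cov / var;
}

// Brandes betweenness (unweighted), node values exclude endpoints.
// Accumulates edge betweenness into a dense matrix.
void betweenness_adj(const AdjList& adj, std::vector<double>& node_bc,
                     NumericMatrix& edge_bc) {
  const int n = static_cast<int>(adj.size());
  node_bc.assign(n, 0.0);
  std::vector<double> sigma(n), delta(n);
  std::vector<int> dist(n);
  std::vector<std::vector<int> > pred(n);
  std::vector<int> order;
  order.reserve(n);
  for (int s = 0; s < n; ++s) {
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(dist.begin(), dist.end(), -1);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int v = 0; v < n; ++v) pred[v].clear();
    order.clear();
    sigma[s] = 1.0;
    dist[s] = 0;
    std::queue<int> Q;
    Q.push(s);
    while (!Q.empty()) {
      int v = Q.front();
      Q.pop();
      order.push_back(v);
      for (int w : adj[v]) {
        if (dist[w] < 0) {
          dist[w] = dist[v] + 1;
          Q.push(w);
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] += sigma[v];
          pred[w].push_back(v);
        }
      }
    }
    for (int idx = static_cast<int>(order.size()) - 1; idx >= 0; --idx) {
      int w = order[idx];
      for (int v : pred[w]) {
        double c = sigma[v] / sigma[w] * (1.0 + delta[w]);
        delta[v] += c;
        edge_bc(v, w) += c;
        edge_bc(w, v) += c;
      }
      if (w != s) node_bc[w] += delta[w];
    }
  }
  // each unordered pair was counted from both endpoints
  for (int v = 0; v < n; ++v) node_bc[v] /= 2.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) edge_bc(i, j) /= 2.0;
}

// --- Louvain ------------------------------------------------------------

// Weighted graph as adjacency maps; self-loop weight stored once at (v,v).
struct WGraph {
  std::vector<std::vector<std::pair<int, double> > > nb;  // no self-loops
  std::vector<double> self_w;
  std::vector<double> ki;  // weighted degree incl. 2*self_w
  double m2;               // sum of ki

  void finalize() {
    const int n = static_cast<int>(nb.size());
    ki.assign(n, 0.0);
    m2 = 0.0;
    for (int v = 0; v < n; ++v) {
      double d = 2.0 * self_w[v];
      for (size_t e = 0; e < nb[v].size(); ++e) d += nb[v][e].second;
      ki[v] = d;
      m2 += d;
    }
  }
};

void shuffle_order(std::vector<int>& v, std::mt19937& rng) {
  // explicit Fisher-Yates: std::shuffle ordering is implementation-defined
  for (int i = static_cast<int>(v.size()) - 1; i > 0; --i) {
    int j = static_cast<int>(rng() % static_cast<uint32_t>(i + 1));
    std::swap(v[i], v[j]);
  }
}

// One local-moving level; returns true if any node changed community.
// `com` supplies the initial assignment (singletons for classic Louvain;
// random partitions on some restarts to escape greedy basins) and holds
// the result.
bool louvain_one_level(const WGraph& g, std::vector<int>& com,
                       std::mt19937& rng) {
  const int n = static_cast<int>(g.nb.size());
  if (static_cast<int>(com.size()) != n) {
    com.resize(n);
    for (int v = 0; v < n; ++v) com[v] = v;
  }
  std::vector<double> tot(n, 0.0);  // community total degree
  for (int v = 0; v < n; ++v) tot[com[v]] += g.ki[v];
  std::vector<double> w_to(n, 0.0);
  std::vector<int> touched;
  std::vector<int> order(n);
  for (int v = 0; v < n; ++v) order[v] = v;

  bool any_move = false;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 100) {
    improved = false;
    ++pass;
    shuffle_order(order, rng);
    for (int oi = 0; oi < n; ++oi) {
      int v = order[oi];
      int old_c = com[v];
      // weights from v to each neighbouring community
      touched.clear();
      for (size_t e = 0; e < g.nb[v].size(); ++e) {
        int c = com[g.nb[v][e].first];
        if (w_to[c] == 0.0) touched.push_back(c);
        w_to[c] += g.nb[v][e].second;
      }
      tot[old_c] -= g.ki[v];
      double best_gain = w_to[old_c] - tot[old_c] * g.ki[v] / g.m2;
      int best_c = old_c;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == old_c) continue;
        double gain = w_to[c] - tot[c] * g.ki[v] / g.m2;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_c = c;
        }
      }
      tot[best_c] += g.ki[v];
      com[v] = best_c;
      if (best_c != old_c) {
        improved = true;
        any_move = true;
      }
      for (size_t t = 0; t < touched.size(); ++t) w_to[touched[t]] = 0.0;
      if (w_to[old_c] != 0.0) w_to[old_c] = 0.0;
    }
  }
  return any_move;
}

void renumber(std::vector<int>& com) {
  std::vector<int> map(com.size(), -1);
  int next = 0;
  for (size_t v = 0; v < com.size(); ++v) {
    if (map[com[v]] < 0) map[com[v]] = next++;
    com[v] = map[com[v]];
  }
}

WGraph aggregate(const WGraph& g, const std::vector<int>& com, int n_com) {
  WGraph out;
  out.nb.assign(n_com, std::vector<std::pair<int, double> >());
  out.self_w.assign(n_com, 0.0);
  const int n = static_cast<int>(g.nb.size());
  std::vector<std::vector<int> > members(n_com);
  for (int v = 0; v < n; ++v) members[com[v]].push_back(v);
  std::vector<double> w_buf(n_com, 0.0);
  std::vector<int> touched;
  for (int c = 0; c < n_com; ++c) {
    touched.clear();
    for (size_t k = 0; k < members[c].size(); ++k) {
      int v = members[c][k];
      out.self_w[c] += g.self_w[v];
      for (size_t e = 0; e < g.nb[v].size(); ++e) {
        int cu = com[g.nb[v][e].first];
        double w = g.nb[v][e].second;
        if (cu == c) {
          out.self_w[c] += w / 2.0;  // both endpoints visited within c
        } else {
          if (w_buf[cu] == 0.0) touched.push_back(cu);
          w_buf[cu] += w;
        }
      }
    }
    for (size_t t = 0; t < touched.size(); ++t) {
      out.nb[c].push_back(std::make_pair(touched[t], w_buf[touched[t]]));
      w_buf[touched[t]] = 0.0;
    }
  }
  out.finalize();
  return out;
}

double binary_modularity(const IntegerMatrix& A,
                         const std::vector<int>& com) {
  const int n = A.nrow();
  double m2 = 0.0;
  std::vector<double> deg(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0) deg[i] += 1.0;
  for (int i = 0; i < n; ++i) m2 += deg[i];
  if (m2 <= 0.0) return 0.0;
  int n_com = 0;
  for (int i = 0; i < n; ++i) n_com = std::max(n_com, com[i] + 1);
  std::vector<double> e_in(n_com, 0.0), d_tot(n_com, 0.0);
  for (int i = 0; i < n; ++i) {
    d_tot[com[i]] += deg[i];
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) != 0 && com[i] == com[j]) e_in[com[i]] += 1.0;
  }
  double m = m2 / 2.0;
  double Q = 0.0;
  for (int c = 0; c < n_com; ++c)
    Q += e_in[c] / m - (d_tot[c] / m2) * (d_tot[c] / m2);
  return Q;
}

// Final refinement: deterministic single-node local moves on the
// original graph until no modularity gain remains.  Louvain's
// aggregation can lock nodes into suboptimal communities on small
// graphs; this pass can only increase Q.
void refine_membership(const WGraph& g, std::vector<int>& com) {
  const int n = static_cast<int>(g.nb.size());
  int n_com = 0;
  for (int v = 0; v < n; ++v) n_com = std::max(n_com, com[v] + 1);
  std::vector<double> tot(n_com + n, 0.0);
  for (int v = 0; v < n; ++v) tot[com[v]] += g.ki[v];
  std::vector<double> w_to(n_com + n, 0.0);
  std::vector<int> touched;
  bool improved = true;
  int pass = 0;
  while (improved && pass < 100) {
    improved = false;
    ++pass;
    for (int v = 0; v < n; ++v) {
      int old_c = com[v];
      touched.clear();
      for (size_t e = 0; e < g.nb[v].size(); ++e) {
        int c = com[g.nb[v][e].first];
        if (w_to[c] == 0.0) touched.push_back(c);
        w_to[c] += g.nb[v][e].second;
      }
      tot[old_c] -= g.ki[v];
      double best_gain = w_to[old_c] - tot[old_c] * g.ki[v] / g.m2;
      int best_c = old_c;
      for (size_t t = 0; t < touched.size(); ++t) {
        int c = touched[t];
        if (c == old_c) continue;
        double gain = w_to[c] - tot[c] * g.ki[v] / g.m2;
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best_c = c;
        }
      }
      tot[best_c] += g.ki[v];
      com[v] = best_c;
      if (best_c != old_c) improved = true;
      for (size_t t = 0; t < touched.size(); ++t) w_to[touched[t]] = 0.0;
      if (w_to[old_c] != 0.0) w_to[old_c] = 0.0;
    }
  }
  renumber(com);
}

// Full Louvain: best partition over n_restarts seeded restarts.
void louvain_binary(const IntegerMatrix& A, int n_restarts,
                    uint32_t seed, std::vector<int>& best_com,
                    double& best_q) {
  const int n = A.nrow();
  WGraph base;
  base.nb.assign(n, std::vector<std::pair<int, double> >());
  base.self_w.assign(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && A(i, j) != 0)
        base.nb[i].push_back(std::make_pair(j, 1.0));
  base.finalize();

  best_com.assign(n, 0);
  best_q = -1.0;
  for (int r = 0; r < n_restarts; ++r) {
    std::mt19937 rng(seed + static_cast<uint32_t>(r) * 2654435769u);
    std::vector<int> membership(n);
    for (int v = 0; v < n; ++v) membership[v] = v;
    WGraph g = base;
    bool moved = true;
    bool first = true;
    while (moved) {
      std::vector<int> com;
      if (first && r % 2 == 1) {
        // random initial partition on alternate restarts: the greedy
        // merge order from singletons cannot reach every optimum
        int K = 1 + static_cast<int>(rng() % static_cast<uint32_t>(n));
        com.resize(n);
        for (int v = 0; v < n; ++v)
          com[v] = static_cast<int>(rng() % static_cast<uint32_t>(K));
      }
      first = false;
      moved = louvain_one_level(g, com, rng);
      renumber(com);
      int n_com = 0;
      for (size_t v = 0; v < com.size(); ++v)
        n_com = std::max(n_com, com[v] + 1);
      for (int v = 0; v < n; ++v) membership[v] = com[membership[v]];
      if (!moved || n_com == static_cast<int>(com.size())) break;
      g = aggregate(g, com, n_com);
    }
    renumber(membership);
    refine_membership(base, membership);
    double q = binary_modularity(A, membership);
    if (q > best_q + 1e-12) {
      best_q = q;
      best_com = membership;
    }
  }
}

bool connected_adj(const AdjList& adj) {
  const int n = static_cast<int>(adj.size());
  if (n == 0) return true;
  std::vector<char> seen(n, 0);
  std::queue<int> Q;
  Q.push(0);
  seen[0] = 1;
  int count = 1;
  while (!Q.empty()) {
    int v = Q.front();
    Q.pop();
    for (int u : adj[v])
      if (!seen[u]) {
        seen[u] = 1;
        ++count;
        Q.push(u);
      }
  }
  return count == n;
}

}  // namespace

// [[Rcpp::export]]
List cpp_edge_order(NumericMatrix R, bool absolute_rank) {
  std::vector<int> oi, oj;
  int n_mst = 0;
  build_edge_order(R, absolute_rank, oi, oj, n_mst);
  IntegerMatrix ord(static_cast<int>(oi.size()), 2);
  for (size_t k = 0; k < oi.size(); ++k) {
    ord(static_cast<int>(k), 0) = oi[k] + 1;  // 1-based for R
    ord(static_cast<int>(k), 1) = oj[k] + 1;
  }
  return List::create(_["order"] = ord, _["n_mst"] = n_mst,
                      _["n_candidates"] = static_cast<int>(oi.size()));
}

// [[Rcpp::export]]
bool cpp_is_connected(IntegerMatrix A) {
  return connected_adj(adj_from_matrix(A));
}

// [[Rcpp::export]]
double cpp_transitivity(IntegerMatrix A) {
  return transitivity_adj(adj_from_matrix(A));
}

// [[Rcpp::export]]
NumericVector cpp_clustering(IntegerMatrix A) {
  std::vector<double> per_node;
  clustering_adj(adj_from_matrix(A), per_node);
  return wrap(per_node);
}

// [[Rcpp::export]]
double cpp_assortativity(IntegerMatrix A) {
  return assortativity_adj(adj_from_matrix(A));
}

// [[Rcpp::export]]
List cpp_betweenness(IntegerMatrix A) {
  const int n = A.nrow();
  AdjList adj = adj_from_matrix(A);
  NumericMatrix ebc(n, n);
  std::vector<double> nbc;
  betweenness_adj(adj, nbc, ebc);
  return List::create(_["node"] = wrap(nbc), _["edge"] = ebc);
}

// [[Rcpp::export]]
List cpp_louvain(IntegerMatrix A, int n_restarts, int seed) {
  std::vector<int> com;
  double q;
  louvain_binary(A, n_restarts, static_cast<uint32_t>(seed), com, q);
  IntegerVector membership(com.begin(), com.end());
  return List::create(_["membership"] = membership, _["Q"] = q);
}

// [[Rcpp::export]]
double cpp_modularity(IntegerMatrix A, IntegerVector membership) {
  std::vector<int> com(membership.begin(), membership.end());
  return binary_modularity(A, com);
}

// Metric columns: 1 modularity, 2 transitivity, 3 assortativity,
// 4 clustering, 5 node_betweenness, 6 edge_betweenness, 7 degree_mean.
// edge_counts: number of edges of the nested network at each density.
// Returns a length(edge_counts) x 7 matrix (NaN for unrequested metrics).
// [[Rcpp::export]]
NumericMatrix cpp_sweep_metrics(NumericMatrix R, IntegerVector edge_counts,
                                LogicalVector want, bool absolute_rank,
                                int n_restarts, int seed) {
  const int n = R.nrow();
  const int D = edge_counts.size();
  std::vector<int> oi, oj;
  int n_mst = 0;
  build_edge_order(R, absolute_rank, oi, oj, n_mst);

  NumericMatrix out(D, 7);
  std::fill(out.begin(), out.end(), NA_REAL);

  IntegerMatrix A(n, n);
  AdjList adj(n);
  int built = 0;
  for (int d = 0; d < D; ++d) {
    int m = edge_counts[d];
    if (m < n - 1 || m > static_cast<int>(oi.size()))
      stop("edge count %d not achievable (have %d candidate edges, need >= %d)",
           m, static_cast<int>(oi.size()), n - 1);
    for (; built < m; ++built) {
      A(oi[built], oj[built]) = 1;
      A(oj[built], oi[built]) = 1;
      adj[oi[built]].push_back(oj[built]);
      adj[oj[built]].push_back(oi[built]);
    }
    if (want[0]) {
      std::vector<int> com;
      double q;
      louvain_binary(A, n_restarts,
                     static_cast<uint32_t>(seed) + 7919u * (d + 1), com, q);
      out(d, 0) = q;
    }
    if (want[1]) out(d, 1) = transitivity_adj(adj);
    if (want[2]) {
      double a = assortativity_adj(adj);
      out(d, 2) = a;
    }
    if (want[3]) {
      std::vector<double> cc;
      clustering_adj(adj, cc);
      double s = 0.0;
      for (size_t v = 0; v < cc.size(); ++v) s += cc[v];
      out(d, 3) = s / n;
    }
    if (want[4] || want[5]) {
      NumericMatrix ebc(n, n);
      std::vector<double> nbc;
      betweenness_adj(adj, nbc, ebc);
      if (want[4]) {
        double s = 0.0;
        double norm = (n - 1.0) * (n - 2.0) / 2.0;
        for (size_t v = 0; v < nbc.size(); ++v) s += nbc[v] / norm;
        out(d, 4) = s / n;
      }
      if (want[5]) {
        double s = 0.0;
        double norm = n * (n - 1.0) / 2.0;
        for (int i = 0; i < n; ++i)
          for (int j = i + 1; j < n; ++j)
            if (A(i, j) != 0) s += ebc(i, j) / norm;
        out(d, 5) = s / m;
      }
    }
    if (want[6]) out(d, 6) = 2.0 * m / n;
  }
  return out;
}

// Connected components of the suprathreshold graph stat > thr.
// Returns per-node component id (0 = not in any suprathreshold edge),
// component extents (edge counts) and intensities (sum of stat).
// [[Rcpp::export]]
List cpp_nbs_components(NumericMatrix stat, double thr) {
  const int n = stat.nrow();
  UnionFind uf(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (stat(i, j) > thr) uf.unite(i, j);
  std::vector<int> comp_id(n, 0);
  std::map<int, int> root_to_id;
  std::vector<double> extent, intensity;
  // only roots that own at least one suprathreshold edge become components
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (stat(i, j) > thr) {
        int r = uf.find(i);
        std::map<int, int>::iterator it = root_to_id.find(r);
        int id;
        if (it == root_to_id.end()) {
          id = static_cast<int>(extent.size()) + 1;
          root_to_id[r] = id;
          extent.push_back(0.0);
          intensity.push_back(0.0);
        } else {
          id = it->second;
        }
        extent[id - 1] += 1.0;
        intensity[id - 1] += stat(i, j);
      }
  for (int i = 0; i < n; ++i) {
    std::map<int, int>::iterator it = root_to_id.find(uf.find(i));
    if (it != root_to_id.end()) comp_id[i] = it->second;
  }
  return List::create(_["component"] = wrap(comp_id),
                      _["extent"] = wrap(extent),
                      _["intensity"] = wrap(intensity));
}

// Maximum component extent (edge count) above threshold — permutation
// null fast path.
// [[Rcpp::export]]
double cpp_nbs_max_extent(NumericMatrix stat, double thr, bool intensity) {
  const int n = stat.nrow();
  UnionFind uf(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (stat(i, j) > thr) uf.unite(i, j);
  std::vector<double> size(n, 0.0);
  double best = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (stat(i, j) > thr) {
        int r = uf.find(i);
        size[r] += intensity ? stat(i, j) : 1.0;
        if (size[r] > best) best = size[r];
      }
  return best;
}
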