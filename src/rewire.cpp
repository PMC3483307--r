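#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving double-edge-swap randomization.
//
// edges: m x 2 integer matrix, 0-based node indices, each row a < b,
// rows unique (a simple undirected graph). Picks two distinct edges
// (a,b),(c,d), proposes one of the two rewirings uniformly
// ((a,d),(c,b) or (a,c),(b,d)), and rejects any proposal that would
// create a self-loop or a duplicate edge. Runs until `target` swaps
// have been ACCEPTED or `cap` proposals have been spent. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export(name = ".rewire_edges_cpp")]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_nodes,
                               double target, double cap) {
  const int m = edges.nrow();
  std::vector<int> ea(m), eb(m);
  std::unordered_set<long long> present;
  present.reserve(m * 2);
  const long long N = n_nodes;
  auto key = [N](int u, int v) -> long long {
    return u < v ? (long long)u * N + v : (long long)v * N + u;
  };
  for (int i = 0; i < m; ++i) {
    ea[i] = edges(i, 0);
    eb[i] = edges(i, 1);
    present.insert(key(ea[i], eb[i]));
  }

  double accepted = 0, proposals = 0;
  if (m >= 2) {
    while (accepted < target && proposals < cap) {
      proposals += 1;
      int i = (int)(unif_rand() * m);
      int j = (int)(unif_rand() * m);
      if (i >= m) i = m - 1;
      if (j >= m) j = m - 1;
      if (i == j) continue;
      int a = ea[i], b = eb[i], c = ea[j], d = eb[j];
      int x1, y1, x2, y2;
      if (unif_rand() < 0.5) {            // (a,d), (c,b)
        x1 = a; y1 = d; x2 = c; y2 = b;
      } else {                            // (a,c), (b,d)
        x1 = a; y1 = c; x2 = b; y2 = d;
      }
      if (x1 == y1 || x2 == y2) continue; // self-loop
      long long k1 = key(x1, y1), k2 = key(x2, y2);
      if (k1 == k2) continue;             // would duplicate each other
      if (present.count(k1) || present.count(k2)) continue;
      present.erase(key(a, b));
      present.erase(key(c, d));
      present.insert(k1);
      present.insert(k2);
      ea[i] = x1 < y1 ? x1 : y1; eb[i] = x1 < y1 ? y1 : x1;
      ea[j] = x2 < y2 ? x2 : y2; eb[j] = x2 < y2 ? y2 : x2;
      accepted += 1;
    }
  }

  IntegerMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    out(i, 0) = ea[i];
    out(i, 1) = eb[i];
  }
  out.attr("accepted") = accepted;
  out.attr("proposals") = proposals;
  return out;
}

// Count edges with one endpoint in A and the other in F (an edge with
// both endpoints in the intersection counts once). in_a / in_f are
// logical membership vectors over node indices.
// [[Rcpp::export(name = ".cross_links_cpp")]]
int cross_links_cpp(IntegerMatrix edges, LogicalVector in_a,
                    LogicalVector in_f) {
  const int m = edges.nrow();
  int n = 0;
  for (int i = 0; i < m; ++i) {
    int u = edges(i, 0), v = edges(i, 1);
    if ((in_a[u] && in_f[v]) || (in_f[u] && in_a[v])) ++n;
  }
  return n;
}
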