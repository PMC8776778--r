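#include <Rcpp.h>
using namespace Rcpp;

// Directed double-edge swaps on a simple digraph.
// edges: 2-column 1-based (from, to). Picks two edges (a->b, c->d) with
// a!=c, b!=d, a!=d, c!=b and neither a->d nor c->b present, and replaces
// them by (a->d, c->b). Degrees, edge count, simplicity are invariant.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n_nodes, int n_swaps,
                               double max_tries) {
  int ne = edges.nrow();
  std::vector<int> from(ne), to(ne);
  std::vector<char> adj((size_t)n_nodes * n_nodes, 0);
  for (int e = 0; e < ne; ++e) {
    from[e] = edges(e, 0) - 1;
    to[e] = edges(e, 1) - 1;
    adj[(size_t)from[e] * n_nodes + to[e]] = 1;
  }
  int done = 0;
  double tries = 0;
  while (done < n_swaps && tries < max_tries) {
    ++tries;
    int e1 = (int)(unif_rand() * ne);
    int e2 = (int)(unif_rand() * ne);
    if (e1 >= ne) e1 = ne - 1;
    if (e2 >= ne) e2 = ne - 1;
    if (e1 == e2) continue;
    int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
    if (a == c || b == d || a == d || c == b) continue;
    if (adj[(size_t)a * n_nodes + d] || adj[(size_t)c * n_nodes + b]) continue;
    adj[(size_t)a * n_nodes + b] = 0;
    adj[(size_t)c * n_nodes + d] = 0;
    adj[(size_t)a * n_nodes + d] = 1;
    adj[(size_t)c * n_nodes + b] = 1;
    to[e1] = d;
    to[e2] = b;
    ++done;
  }
  IntegerMatrix out(ne, 2);
  for (int e = 0; e < ne; ++e) {
    out(e, 0) = from[e] + 1;
    out(e, 1) = to[e] + 1;
  }
  return out;
}
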