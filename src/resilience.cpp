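#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Monte-Carlo entropy of component sizes under random node failure.
//
// The failure grid is f_k = k/K for k = 0..K-1 (f = 1 excluded); at each
// rate floor(f_k * n) nodes are removed uniformly without replacement.
// Rather than drawing an independent subset for every (k, replicate) pair,
// each replicate draws one random removal permutation and the grid points
// are read off as checkpoints along it -- distributionally identical and
// O(n + E) per replicate via reverse node addition with union-find.
//
// Entropy bookkeeping: H_raw = ln(n_rem) - S/n_rem with S = sum_i c_i ln c_i
// over component sizes c_i; H_norm = H_raw / ln(n_rem), defined as 0 when
// n_rem <= 1 (and automatically 0 for a single component).
//
// Uses R's RNG (unif_rand) so results are reproducible under set.seed().
//
// edges: E x 2 integer matrix, 0-based node indices, no self loops.
// Returns a K x M matrix of normalized entropies.
// [[Rcpp::export]]
NumericMatrix mc_failure_entropy(int n, IntegerMatrix edges, int K, int M) {
  if (n < 1) stop("network must have at least one node");
  if (K < 2) stop("failure grid needs K >= 2");
  if (M < 1) stop("need at least one Monte-Carlo replicate");

  const int E = edges.nrow();
  // adjacency in CSR form
  std::vector<int> deg(n, 0);
  for (int e = 0; e < E; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  std::vector<int> off(n + 1, 0);
  for (int v = 0; v < n; ++v) off[v + 1] = off[v] + deg[v];
  std::vector<int> adj(off[n]);
  std::vector<int> cur(off.begin(), off.end() - 1);
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[cur[a]++] = b;
    adj[cur[b]++] = a;
  }

  // checkpoint alive-counts per grid index: alive_k = n - floor(f_k * n),
  // with floor(k/K * n) computed exactly as integer division k*n/K
  std::vector<int> alive_at(K);
  for (int k = 0; k < K; ++k)
    alive_at[k] = n - (int)(((long long)k * n) / K);

  NumericMatrix out(K, M);
  std::vector<int> perm(n), parent(n), csize(n);
  std::vector<char> active(n);

  for (int m = 0; m < M; ++m) {
    // removal order: Fisher-Yates using R's RNG
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    std::fill(active.begin(), active.end(), 0);
    double S = 0.0;  // sum c_i ln c_i
    int alive = 0;

    // grid index K-1 has the fewest survivors; walk k downward while adding
    // nodes back in reverse removal order
    int k = K - 1;
    // checkpoints with alive_at == 0 impossible (floor(f*n) < n for f < 1)
    for (int pos = n - 1; pos >= -1; --pos) {
      while (k >= 0 && alive_at[k] == alive) {
        double H = 0.0;
        if (alive > 1) {
          double ln_n = std::log((double)alive);
          H = (ln_n - S / alive) / ln_n;
          if (H < 0.0) H = 0.0;
          if (H > 1.0) H = 1.0;
        }
        out(k, m) = H;
        --k;
      }
      if (pos < 0) break;
      // activate node perm[pos]
      int v = perm[pos];
      active[v] = 1;
      parent[v] = v;
      csize[v] = 1;
      ++alive;
      for (int t = off[v]; t < off[v + 1]; ++t) {
        int u = adj[t];
        if (!active[u]) continue;
        // find roots with path halving
        int ra = v, rb = u;
        while (parent[ra] != ra) { parent[ra] = parent[parent[ra]]; ra = parent[ra]; }
        while (parent[rb] != rb) { parent[rb] = parent[parent[rb]]; rb = parent[rb]; }
        if (ra == rb) continue;
        int ca = csize[ra], cb = csize[rb];
        S += (double)(ca + cb) * std::log((double)(ca + cb));
        if (ca > 1) S -= (double)ca * std::log((double)ca);
        if (cb > 1) S -= (double)cb * std::log((double)cb);
        if (ca < cb) std::swap(ra, rb);
        parent[rb] = ra;
        csize[ra] = ca + cb;
      }
    }
    if (k >= 0) stop("internal error: unreached failure-grid checkpoint");
  }
  return out;
}
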