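#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Degree-preserving edge-swap MCMC over simple undirected graphs.
//
// State: edge list of a simple graph. Move: pick an ordered pair of distinct
// edges {a,b},{c,d} and one of the two pairings ({a,d},{c,b}) or
// ({a,c},{b,d}); execute it iff it creates no self-loop and no duplicate
// edge. The candidate set (pairs x pairings) has constant size 2*E*(E-1)/2
// in every state, so with "hold counting" (invalid proposals executed as
// stay-moves) the chain is symmetric and its stationary distribution is
// uniform over all simple graphs with the given degree sequence. The
// alternative "mobility ratio" mode accepts an executable move from c to c'
// with probability min(1, n(c)/n(c')), n(.) = number of executable swaps,
// which also targets the uniform measure; it costs O(E^2) per proposal and
// is intended for small graphs and cross-checks.

typedef long long ll;

static inline ll key_of(int a, int b, int n) {
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (ll)lo * (ll)n + (ll)hi;
}

// number of executable swap moves from the current state (mobility n(c))
static int count_moves(const std::vector<int>& u, const std::vector<int>& v,
                       const std::unordered_set<ll>& present, int n) {
  int E = (int)u.size(), cnt = 0;
  for (int i = 0; i < E - 1; ++i) {
    for (int j = i + 1; j < E; ++j) {
      int a = u[i], b = v[i], c = u[j], d = v[j];
      // pairing 1: {a,d},{c,b}
      if (a != d && c != b &&
          !present.count(key_of(a, d, n)) && !present.count(key_of(c, b, n)))
        ++cnt;
      // pairing 2: {a,c},{b,d}
      if (a != c && b != d &&
          !present.count(key_of(a, c, n)) && !present.count(key_of(b, d, n)))
        ++cnt;
    }
  }
  return cnt;
}

static std::string signature(const std::vector<int>& u,
                             const std::vector<int>& v, int n) {
  std::vector<ll> keys(u.size());
  for (size_t i = 0; i < u.size(); ++i) keys[i] = key_of(u[i], v[i], n);
  std::sort(keys.begin(), keys.end());
  std::string s;
  for (size_t i = 0; i < keys.size(); ++i) {
    if (i) s += ',';
    s += std::to_string(keys[i]);
  }
  return s;
}

// [[Rcpp::export]]
List cpp_mcmc(IntegerMatrix edges, int n_nodes, double target_accepted,
              int mode, int monitor_every, int sample_every,
              double max_proposals) {
  int E = edges.nrow();
  std::vector<int> u(E), v(E);
  std::unordered_set<ll> present, original;
  std::vector<double> deg(n_nodes, 0.0);
  for (int i = 0; i < E; ++i) {
    u[i] = edges(i, 0); v[i] = edges(i, 1);
    present.insert(key_of(u[i], v[i], n_nodes));
    original.insert(key_of(u[i], v[i], n_nodes));
    deg[u[i]] += 1.0; deg[v[i]] += 1.0;
  }
  // fixed edge-end moments for the assortativity trace
  double mu = 0.0, m2 = 0.0, Se = 0.0;
  for (int i = 0; i < n_nodes; ++i) { mu += deg[i] * deg[i]; m2 += deg[i] * deg[i] * deg[i]; }
  mu /= (2.0 * E); m2 /= (2.0 * E);
  double var = m2 - mu * mu;
  for (int i = 0; i < E; ++i) Se += deg[u[i]] * deg[v[i]];
  long overlap = E;  // edges shared with the original graph

  double accepted = 0.0, proposed = 0.0;
  std::vector<double> tr_acc, tr_assort, tr_ham;
  std::vector<std::string> sigs;
  double next_monitor = monitor_every > 0 ? monitor_every : -1.0;
  double next_sample = sample_every > 0 ? sample_every : -1.0;
  bool stalled = false;

  auto log_trace = [&]() {
    tr_acc.push_back(accepted);
    tr_assort.push_back(var > 0 ? (Se / E - mu * mu) / var : NA_REAL);
    tr_ham.push_back((double)(E - overlap) / (double)E);
  };
  log_trace();

  while (accepted < target_accepted) {
    if (proposed >= max_proposals) { stalled = true; break; }
    proposed += 1.0;
    int i = (int)(R::unif_rand() * E); if (i >= E) i = E - 1;
    int j = (int)(R::unif_rand() * (E - 1)); if (j >= E - 1) j = E - 2;
    if (j >= i) ++j;
    bool pairing1 = R::unif_rand() < 0.5;
    int a = u[i], b = v[i], c = u[j], d = v[j];
    int x1, y1, x2, y2;  // replacement edges for i and j
    if (pairing1) { x1 = a; y1 = d; x2 = c; y2 = b; }
    else          { x1 = a; y1 = c; x2 = b; y2 = d; }
    bool ok = (x1 != y1) && (x2 != y2) &&
      !present.count(key_of(x1, y1, n_nodes)) &&
      !present.count(key_of(x2, y2, n_nodes));
    if (ok && mode == 1) {
      int n_cur = count_moves(u, v, present, n_nodes);
      // tentatively apply to count n(proposed)
      ll ko1 = key_of(a, b, n_nodes), ko2 = key_of(c, d, n_nodes);
      ll kn1 = key_of(x1, y1, n_nodes), kn2 = key_of(x2, y2, n_nodes);
      present.erase(ko1); present.erase(ko2);
      present.insert(kn1); present.insert(kn2);
      u[i] = std::min(x1, y1); v[i] = std::max(x1, y1);
      u[j] = std::min(x2, y2); v[j] = std::max(x2, y2);
      int n_new = count_moves(u, v, present, n_nodes);
      bool keep = R::unif_rand() < std::min(1.0, (double)n_cur / (double)n_new);
      if (!keep) {  // revert
        present.erase(kn1); present.erase(kn2);
        present.insert(ko1); present.insert(ko2);
        u[i] = std::min(a, b); v[i] = std::max(a, b);
        u[j] = std::min(c, d); v[j] = std::max(c, d);
        ok = false;
      } else {
        Se += deg[x1] * deg[y1] + deg[x2] * deg[y2]
            - deg[a] * deg[b] - deg[c] * deg[d];
        overlap += (original.count(kn1) ? 1 : 0) + (original.count(kn2) ? 1 : 0)
                 - (original.count(ko1) ? 1 : 0) - (original.count(ko2) ? 1 : 0);
        accepted += 1.0;
        ok = false;  // already applied
      }
    } else if (ok) {
      ll ko1 = key_of(a, b, n_nodes), ko2 = key_of(c, d, n_nodes);
      ll kn1 = key_of(x1, y1, n_nodes), kn2 = key_of(x2, y2, n_nodes);
      present.erase(ko1); present.erase(ko2);
      present.insert(kn1); present.insert(kn2);
      u[i] = std::min(x1, y1); v[i] = std::max(x1, y1);
      u[j] = std::min(x2, y2); v[j] = std::max(x2, y2);
      Se += deg[x1] * deg[y1] + deg[x2] * deg[y2]
          - deg[a] * deg[b] - deg[c] * deg[d];
      overlap += (original.count(kn1) ? 1 : 0) + (original.count(kn2) ? 1 : 0)
               - (original.count(ko1) ? 1 : 0) - (original.count(ko2) ? 1 : 0);
      accepted += 1.0;
    }
    if (next_monitor > 0 && accepted >= next_monitor) {
      log_trace();
      next_monitor += monitor_every;
    }
    if (next_sample > 0 && proposed >= next_sample) {
      sigs.push_back(signature(u, v, n_nodes));
      next_sample += sample_every;
    }
  }
  log_trace();

  IntegerMatrix out(E, 2);
  for (int i = 0; i < E; ++i) { out(i, 0) = u[i]; out(i, 1) = v[i]; }
  return List::create(
    _["edges"] = out,
    _["accepted"] = accepted,
    _["proposed"] = proposed,
    _["stalled"] = stalled,
    _["hamming"] = (double)(E - overlap) / (double)E,
    _["trace_accepted"] = wrap(tr_acc),
    _["trace_assortativity"] = wrap(tr_assort),
    _["trace_hamming"] = wrap(tr_ham),
    _["signatures"] = wrap(sigs));
}

// Biased edge swaps driving the edge degree-product sum Se towards a target
// (assortativity is affine in Se at fixed degree sequence). Accepts any swap
// that does not increase |Se - target|; stops inside the tolerance band.
// [[Rcpp::export]]
List cpp_drive_assortativity(IntegerMatrix edges, int n_nodes,
                             double target_Se, double band,
                             double max_proposals) {
  int E = edges.nrow();
  std::vector<int> u(E), v(E);
  std::unordered_set<ll> present;
  std::vector<double> deg(n_nodes, 0.0);
  for (int i = 0; i < E; ++i) {
    u[i] = edges(i, 0); v[i] = edges(i, 1);
    present.insert(key_of(u[i], v[i], n_nodes));
    deg[u[i]] += 1.0; deg[v[i]] += 1.0;
  }
  double Se = 0.0, proposed = 0.0;
  for (int i = 0; i < E; ++i) Se += deg[u[i]] * deg[v[i]];
  while (std::fabs(Se - target_Se) > band && proposed < max_proposals) {
    proposed += 1.0;
    int i = (int)(R::unif_rand() * E); if (i >= E) i = E - 1;
    int j = (int)(R::unif_rand() * (E - 1)); if (j >= E - 1) j = E - 2;
    if (j >= i) ++j;
    bool pairing1 = R::unif_rand() < 0.5;
    int a = u[i], b = v[i], c = u[j], d = v[j];
    int x1, y1, x2, y2;
    if (pairing1) { x1 = a; y1 = d; x2 = c; y2 = b; }
    else          { x1 = a; y1 = c; x2 = b; y2 = d; }
    if (x1 == y1 || x2 == y2) continue;
    ll kn1 = key_of(x1, y1, n_nodes), kn2 = key_of(x2, y2, n_nodes);
    if (present.count(kn1) || present.count(kn2)) continue;
    double dS = deg[x1] * deg[y1] + deg[x2] * deg[y2]
              - deg[a] * deg[b] - deg[c] * deg[d];
    if (std::fabs(Se + dS - target_Se) <= std::fabs(Se - target_Se)) {
      present.erase(key_of(a, b, n_nodes));
      present.erase(key_of(c, d, n_nodes));
      present.insert(kn1); present.insert(kn2);
      u[i] = std::min(x1, y1); v[i] = std::max(x1, y1);
      u[j] = std::min(x2, y2); v[j] = std::max(x2, y2);
      Se += dS;
    }
  }
  IntegerMatrix out(E, 2);
  for (int i = 0; i < E; ++i) { out(i, 0) = u[i]; out(i, 1) = v[i]; }
  return List::create(
    _["edges"] = out,
    _["Se"] = Se,
    _["proposed"] = proposed,
    _["reached"] = std::fabs(Se - target_Se) <= band);
}
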