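// Degree-preserving double-edge-swap sampler with simulated annealing on the
// degree Pearson correlation r (degree assortativity).
//
// A proposal picks two random edges A-B and C-D (each orientation randomly
// flipped) and rewires them to A-C and B-D. Degrees never change, so the
// degree sums entering r are fixed and only the sum of endpoint-degree
// products changes; r updates in O(1) using exact integer arithmetic, so
// there is no drift to correct. Improvements in the configured objective are
// always accepted; worsening moves are accepted with probability
// exp(-gamma * |worsening|), where 1/gamma is the annealing temperature.
// Connectivity is re-checked by BFS every conn_interval steps, rolling back
// to the last verified state on failure.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <unordered_set>
#include <vector>

using namespace Rcpp;

namespace {

struct EdgeState {
  std::vector<int> u, v;           // current edge endpoints (0-based)
  long long se = 0;                // sum over edges of deg[u]*deg[v]
};

struct SwapRng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  explicit SwapRng(std::uint64_t seed) { eng.seed(seed * 0x9E3779B97F4A7C15ULL + 0x2545F4914F6CDD1DULL); }
  double u() { return unif(eng); }
  int ui(int n) { return (int)(eng() % (std::uint64_t)n); }
};

inline std::uint64_t ekey(int a, int b) {
  if (a > b) std::swap(a, b);
  return ((std::uint64_t)a << 32) | (std::uint64_t)b;
}

bool connected(int n, const EdgeState& es) {
  std::vector<std::vector<int>> adj(n);
  for (size_t e = 0; e < es.u.size(); ++e) {
    adj[es.u[e]].push_back(es.v[e]);
    adj[es.v[e]].push_back(es.u[e]);
  }
  std::vector<char> seen(n, 0);
  std::vector<int> stack{0};
  seen[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int x = stack.back();
    stack.pop_back();
    for (int y : adj[x])
      if (!seen[y]) { seen[y] = 1; ++cnt; stack.push_back(y); }
  }
  return cnt == n;
}

} // namespace

// [[Rcpp::export]]
List cpp_anneal_assortativity(IntegerMatrix edges, int n_nodes, bool maximize,
                              NumericVector gamma_schedule, double total_steps,
                              double checkpoint_interval, double conn_interval,
                              double seed) {
  const int m = edges.nrow();
  std::vector<int> deg(n_nodes, 0);
  EdgeState cur;
  cur.u.resize(m); cur.v.resize(m);
  std::unordered_set<std::uint64_t> eset;
  eset.reserve(2 * m);
  for (int e = 0; e < m; ++e) {
    cur.u[e] = edges(e, 0); cur.v[e] = edges(e, 1);
    ++deg[cur.u[e]]; ++deg[cur.v[e]];
    eset.insert(ekey(cur.u[e], cur.v[e]));
  }
  long long s1 = 0, s2 = 0;
  for (int e = 0; e < m; ++e) {
    s1 += deg[cur.u[e]] + deg[cur.v[e]];
    s2 += (long long)deg[cur.u[e]] * deg[cur.u[e]] +
          (long long)deg[cur.v[e]] * deg[cur.v[e]];
    cur.se += (long long)deg[cur.u[e]] * deg[cur.v[e]];
  }
  const double mu = (double)s1 / (2.0 * m);
  const double var = (double)s2 / (2.0 * m) - mu * mu;
  auto r_of = [&](long long se) { return ((double)se / m - mu * mu) / var; };

  double r_cur = r_of(cur.se);
  const double r_initial = r_cur;
  EdgeState verified = cur;                 // last connectivity-verified state
  std::unordered_set<std::uint64_t> verified_eset = eset;
  EdgeState best = cur;
  double r_best = r_cur;

  std::vector<double> traj_step, traj_r;
  std::vector<int> traj_accepted;
  List checkpoints;
  std::vector<double> checkpoint_steps, checkpoint_r;

  const long long n_steps = (long long)total_steps;
  const long long ckpt_iv = (long long)checkpoint_interval;
  const long long conn_iv = (long long)conn_interval;
  const int n_stages = gamma_schedule.size();
  const long long stage_len = std::max(1LL, n_steps / n_stages);
  SwapRng rng((std::uint64_t)seed);
  double n_accepted = 0, n_rejected = 0;

  auto snapshot_edges = [&](const EdgeState& es) {
    IntegerMatrix out(m, 2);
    for (int e = 0; e < m; ++e) { out(e, 0) = es.u[e]; out(e, 1) = es.v[e]; }
    return out;
  };

  for (long long step = 1; step <= n_steps; ++step) {
    double gamma = gamma_schedule[std::min((long long)n_stages - 1, (step - 1) / stage_len)];
    int e1 = rng.ui(m), e2 = rng.ui(m);
    bool accepted = false;
    if (e1 != e2) {
      int a = cur.u[e1], b = cur.v[e1], c = cur.u[e2], d = cur.v[e2];
      if (rng.u() < 0.5) std::swap(a, b);
      if (rng.u() < 0.5) std::swap(c, d);
      // propose A-C, B-D
      bool degenerate = (a == c || a == d || b == c || b == d) ||
                        eset.count(ekey(a, c)) || eset.count(ekey(b, d));
      if (!degenerate) {
        long long dse = (long long)deg[a] * deg[c] + (long long)deg[b] * deg[d] -
                        (long long)deg[a] * deg[b] - (long long)deg[c] * deg[d];
        double r_new = r_of(cur.se + dse);
        double delta = maximize ? (r_new - r_cur) : (r_cur - r_new);
        if (delta >= 0 || rng.u() < std::exp(gamma * delta)) {
          eset.erase(ekey(a, b)); eset.erase(ekey(c, d));
          eset.insert(ekey(a, c)); eset.insert(ekey(b, d));
          cur.u[e1] = a; cur.v[e1] = c;
          cur.u[e2] = b; cur.v[e2] = d;
          cur.se += dse;
          r_cur = r_new;
          accepted = true;
        }
      }
    }
    if (accepted) ++n_accepted; else ++n_rejected;

    bool better = maximize ? (r_cur > r_best) : (r_cur < r_best);
    if (better) { best = cur; r_best = r_cur; }

    if (step % conn_iv == 0) {
      if (connected(n_nodes, cur)) {
        verified = cur;
        verified_eset = eset;
      } else {
        cur = verified;
        eset = verified_eset;
        r_cur = r_of(cur.se);
        if ((maximize && r_best > r_cur) || (!maximize && r_best < r_cur)) {
          if (!connected(n_nodes, best)) { best = cur; r_best = r_cur; }
        }
      }
    }
    if (step % ckpt_iv == 0) {
      checkpoints.push_back(snapshot_edges(cur));
      checkpoint_steps.push_back((double)step);
      checkpoint_r.push_back(r_cur);
      traj_step.push_back((double)step);
      traj_r.push_back(r_cur);
      traj_accepted.push_back(accepted ? 1 : 0);
    }
  }

  // final states must be connected: fall back to last verified if not
  if (!connected(n_nodes, cur)) { cur = verified; r_cur = r_of(cur.se); }
  if (!connected(n_nodes, best)) { best = cur; r_best = r_cur; }

  return List::create(
      _["final_edges"] = snapshot_edges(cur), _["final_r"] = r_cur,
      _["best_edges"] = snapshot_edges(best), _["best_r"] = r_best,
      _["initial_r"] = r_initial, _["checkpoints"] = checkpoints,
      _["checkpoint_steps"] = NumericVector(checkpoint_steps.begin(), checkpoint_steps.end()),
      _["checkpoint_r"] = NumericVector(checkpoint_r.begin(), checkpoint_r.end()),
      _["traj_accepted"] = IntegerVector(traj_accepted.begin(), traj_accepted.end()),
      _["n_accepted"] = n_accepted, _["n_rejected"] = n_rejected);
}
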