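// Monte Carlo core of the Moran process on graphs.
//
// Each replicate starts with a single mutant (fitness 1 + s, wild type 1) and
// runs to absorption under the Birth-death (Bd) or death-Birth (dB) update
// rule. Replicates use independent RNG streams derived from (seed, replicate
// index) via splitmix64, so any single replicate is reproducible in
// isolation and results do not depend on R's global RNG state.

#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

static inline std::uint64_t splitmix64(std::uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct RepRng {
  std::mt19937_64 eng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};
  RepRng(std::uint64_t seed, std::uint64_t rep) {
    std::uint64_t s = splitmix64(seed ^ splitmix64(rep + 0x51ED2701ULL));
    eng.seed(s);
  }
  double u() { return unif(eng); }
  // uniform integer in [0, n)
  int ui(int n) { return (int)(eng() % (std::uint64_t)n); }
};

// Membership bookkeeping: mutant/wild-type node lists with position index so
// both fitness-proportional (two types) and uniform choices are O(1).
struct Pop {
  int n;
  std::vector<std::uint8_t> mut;
  std::vector<int> mutlist, wtlist, pos;
  int m; // mutant count

  void init(int n_, int start) {
    n = n_;
    mut.assign(n, 0);
    mutlist.clear();
    wtlist.resize(0);
    pos.assign(n, 0);
    for (int v = 0; v < n; ++v)
      if (v != start) {
        pos[v] = (int)wtlist.size();
        wtlist.push_back(v);
      }
    mut[start] = 1;
    pos[start] = 0;
    mutlist.push_back(start);
    m = 1;
  }

  void flip(int v) {
    if (mut[v]) {
      int p = pos[v], last = mutlist.back();
      mutlist[p] = last;
      pos[last] = p;
      mutlist.pop_back();
      mut[v] = 0;
      pos[v] = (int)wtlist.size();
      wtlist.push_back(v);
      --m;
    } else {
      int p = pos[v], last = wtlist.back();
      wtlist[p] = last;
      pos[last] = p;
      wtlist.pop_back();
      mut[v] = 1;
      pos[v] = (int)mutlist.size();
      mutlist.push_back(v);
      ++m;
    }
  }
};

// [[Rcpp::export]]
List cpp_simulate_fixation(IntegerVector offsets, IntegerVector neighbors,
                           int rule, double s, int reps, double seed,
                           IntegerVector init_nodes, double step_cap) {
  const int n = offsets.size() - 1;
  const double fm = 1.0 + s;
  std::uint64_t useed = (std::uint64_t)seed;

  int n_fixed = 0, n_lost = 0, n_capped = 0;
  std::vector<double> steps_fixed;
  Pop pop;

  for (int rep = 0; rep < reps; ++rep) {
    RepRng rng(useed, (std::uint64_t)rep);
    int start = init_nodes[init_nodes.size() == 1 ? 0 : rng.ui(init_nodes.size())];
    pop.init(n, start);
    double steps = 0.0;
    bool capped = false;

    while (pop.m > 0 && pop.m < n) {
      if (steps >= step_cap) { capped = true; break; }
      ++steps;
      if (rule == 0) {
        // Bd: reproducer fitness-proportional over everyone, victim uniform
        // among its neighbours.
        double W = (double)(n - pop.m) + fm * (double)pop.m;
        int parent;
        if (rng.u() * W < fm * (double)pop.m)
          parent = pop.mutlist[rng.ui(pop.m)];
        else
          parent = pop.wtlist[rng.ui(n - pop.m)];
        int deg = offsets[parent + 1] - offsets[parent];
        int victim = neighbors[offsets[parent] + rng.ui(deg)];
        if (pop.mut[victim] != pop.mut[parent]) pop.flip(victim);
      } else {
        // dB: victim uniform over everyone, reproducer fitness-proportional
        // among the victim's neighbours.
        int victim = rng.ui(n);
        int lo = offsets[victim], hi = offsets[victim + 1];
        int k = 0;
        for (int t = lo; t < hi; ++t) k += pop.mut[neighbors[t]];
        int deg = hi - lo;
        double wtot = fm * (double)k + (double)(deg - k);
        std::uint8_t ptype = (rng.u() * wtot < fm * (double)k) ? 1 : 0;
        if (pop.mut[victim] != ptype) pop.flip(victim);
      }
    }

    if (capped) {
      ++n_capped;
    } else if (pop.m == n) {
      ++n_fixed;
      steps_fixed.push_back(steps);
    } else {
      ++n_lost;
    }
  }

  return List::create(_["n_fixed"] = n_fixed, _["n_lost"] = n_lost,
                      _["n_capped"] = n_capped,
                      _["steps_fixed"] = NumericVector(steps_fixed.begin(),
                                                       steps_fixed.end()));
}
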