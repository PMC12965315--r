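// Agent-based Monte Carlo simulation of public-goods-game strategy
// evolution. One elementary step updates at most one node; a full Monte
// Carlo step is N elementary steps. Runs start from a single cooperator at
// a uniform node and stop at fixation or after max_mcs full steps.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// xoshiro256++ with splitmix64 seeding: deterministic across platforms,
// one independent stream per run derived from (seed, run index).
struct Rng {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  Rng(uint64_t seed, uint64_t stream) {
    uint64_t x = seed * 0x9e3779b97f4a7c15ULL + stream;
    for (int i = 0; i < 4; i++) s[i] = splitmix(x);
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int below(int n) { return (int)(unif() * n) % n; }
};

// payoff of node i: sum over games organised by l in {i} u N(i) of
// r*c*coop_in_group(l)/G_l minus own cost per game; averaged over G_i games
// for the average scheme.
static inline double payoff(int i, const std::vector<int> &x,
                            const std::vector<int> &cg,
                            const std::vector<std::vector<int>> &nbr,
                            const std::vector<double> &Ginv, bool average,
                            double r, double cost) {
  double f = r * cost * cg[i] * Ginv[i];
  const std::vector<int> &ni = nbr[i];
  for (size_t q = 0; q < ni.size(); q++) {
    int l = ni[q];
    f += r * cost * cg[l] * Ginv[l];
  }
  double Gi = (double)ni.size() + 1.0;
  f -= x[i] * cost * Gi;
  if (average) f /= Gi;
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_simulate_runs(IntegerMatrix adjacency, int rule,
                                bool average, double r, double cost,
                                double delta, int n_runs, int max_mcs,
                                int seed) {
  int n = adjacency.nrow();
  std::vector<std::vector<int>> nbr(n);
  for (int i = 0; i < n; i++)
    for (int j = 0; j < n; j++)
      if (adjacency(i, j) == 1) nbr[i].push_back(j);
  std::vector<double> Ginv(n);
  for (int i = 0; i < n; i++) Ginv[i] = 1.0 / (nbr[i].size() + 1.0);

  NumericVector out(n_runs);
  std::vector<int> x(n), cg(n);
  std::vector<double> fit(n);
  long long max_steps = (long long)max_mcs * n;

  for (int run = 0; run < n_runs; run++) {
    Rng rng((uint64_t)seed, (uint64_t)run + 1);
    std::fill(x.begin(), x.end(), 0);
    std::fill(cg.begin(), cg.end(), 0);
    int first = rng.below(n);
    x[first] = 1;
    cg[first] += 1;
    for (size_t q = 0; q < nbr[first].size(); q++) cg[nbr[first][q]] += 1;
    int ncoop = 1;

    for (long long step = 0; step < max_steps; step++) {
      int i = -1, j = -1;
      if (rule == 0) { // PC: focal imitates a uniform neighbour (Fermi)
        i = rng.below(n);
        j = nbr[i][rng.below((int)nbr[i].size())];
        if (x[i] == x[j]) continue;
        double fi = payoff(i, x, cg, nbr, Ginv, average, r, cost);
        double fj = payoff(j, x, cg, nbr, Ginv, average, r, cost);
        double p = 1.0 / (1.0 + std::exp(-delta * (fj - fi)));
        if (rng.unif() >= p) continue;
      } else if (rule == 1) { // DB: neighbours compete for the vacancy
        i = rng.below(n);
        const std::vector<int> &ni = nbr[i];
        double tot = 0.0;
        for (size_t q = 0; q < ni.size(); q++) {
          double fj = payoff(ni[q], x, cg, nbr, Ginv, average, r, cost);
          fit[q] = std::exp(delta * fj);
          tot += fit[q];
        }
        double u = rng.unif() * tot;
        size_t q = 0;
        for (; q + 1 < ni.size(); q++) {
          if (u < fit[q]) break;
          u -= fit[q];
        }
        j = ni[q];
        if (x[i] == x[j]) continue;
      } else { // BD: global fitness-proportional birth, random neighbour dies
        double tot = 0.0;
        for (int v = 0; v < n; v++) {
          double fv = payoff(v, x, cg, nbr, Ginv, average, r, cost);
          fit[v] = std::exp(delta * fv);
          tot += fit[v];
        }
        double u = rng.unif() * tot;
        int v = 0;
        for (; v + 1 < n; v++) {
          if (u < fit[v]) break;
          u -= fit[v];
        }
        j = v;
        i = nbr[j][rng.below((int)nbr[j].size())];
        if (x[i] == x[j]) continue;
      }
      // flip node i to x[j]
      int d = x[j] - x[i];
      x[i] = x[j];
      ncoop += d;
      cg[i] += d;
      for (size_t q = 0; q < nbr[i].size(); q++) cg[nbr[i][q]] += d;
      if (ncoop == 0 || ncoop == n) break;
    }
    out[run] = (double)ncoop / n;
  }
  return out;
}
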