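// Discrete-time-slice simulator of RNAP traffic on an N-nt template across
// many cells, with a minimum center-to-center spacing constraint (collision
// exclusion). Each slice, every RNAP advances by at most one nucleotide with
// probability rate * dt (Bernoulli approximation to exponential waiting
// times); an advance is cancelled if it would bring the RNAP closer than s_p
// to the next downstream RNAP. A free landing pad (no RNAP at position
// <= s_p) admits a new initiation event with probability alpha_zeta * dt.
// An RNAP at its cell's pause site advances at beta_zeta * dt; advancing
// past N removes it from the template.
//
// Within a slice, RNAPs in a cell are updated from most-downstream to
// most-upstream using current positions, so space freed in a slice is
// usable in the same slice.

#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// xorshift128+ with splitmix64 seeding: fast, reproducible across platforms
struct Rng {
  uint64_t s0, s1;
  explicit Rng(uint64_t seed) {
    uint64_t z = seed;
    auto next = [&z]() {
      z += 0x9E3779B97f4A7C15ULL;
      uint64_t w = z;
      w = (w ^ (w >> 30)) * 0xBF58476D1CE4E5B9ULL;
      w = (w ^ (w >> 27)) * 0x94D049BB133111EBULL;
      return w ^ (w >> 31);
    };
    s0 = next(); s1 = next();
    if (s0 == 0 && s1 == 0) s0 = 1;
  }
  inline uint64_t next() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// [[Rcpp::export(name = ".simulate_cells_cpp")]]
List simulate_cells_cpp(int n_cells, int template_len, double steps_total,
                        double steps_burnin, double dt, double alpha_zeta,
                        double beta_zeta, NumericVector zeta,
                        IntegerVector pause_site, int s_p, double seed,
                        bool check_spacing) {
  const int N = template_len, C = n_cells;
  if (zeta.size() != N) stop("zeta must have one rate per position");
  if (pause_site.size() != C) stop("one pause site per cell required");
  const double p_init = alpha_zeta * dt;
  const double p_escape = beta_zeta * dt;
  std::vector<double> p_adv(N);
  for (int i = 0; i < N; ++i) {
    p_adv[i] = zeta[i] * dt;
    if (p_adv[i] >= 1.0) stop("rate * dt >= 1: time slice too coarse");
  }
  if (p_init >= 1.0 || p_escape >= 1.0)
    stop("rate * dt >= 1: time slice too coarse");

  Rng rng(static_cast<uint64_t>(seed));

  // per-cell RNAP positions, ascending (index 0 = most upstream)
  const int maxp = N / s_p + 2;
  std::vector<int> pos(static_cast<size_t>(C) * maxp, 0);
  std::vector<int> cnt(C, 0);
  double n_success = 0.0, n_blocked = 0.0;
  const double total = steps_total;

  for (double step = 0.0; step < total; step += 1.0) {
    if (step == steps_burnin) { n_success = 0.0; n_blocked = 0.0; }
    for (int c = 0; c < C; ++c) {
      int *p = &pos[static_cast<size_t>(c) * maxp];
      int n = cnt[c];
      const int ksite = pause_site[c];
      // downstream to upstream
      for (int j = n - 1; j >= 0; --j) {
        const int at = p[j];
        const double pr = (at == ksite) ? p_escape : p_adv[at - 1];
        if (rng.unif() < pr) {
          if (at == N) {           // termination: leave the template
            --n;                   // most-downstream is last; shift left
            for (int m = j; m < n; ++m) p[m] = p[m + 1];
          } else if (j == n - 1 || p[j + 1] - (at + 1) >= s_p) {
            p[j] = at + 1;
          }                        // else blocked by downstream neighbour
        }
      }
      // initiation attempt
      if (rng.unif() < p_init) {
        if (n > 0 && p[0] <= s_p) {
          n_blocked += 1.0;
        } else if (n < maxp) {
          for (int m = n; m > 0; --m) p[m] = p[m - 1];
          p[0] = 1;
          ++n;
          n_success += 1.0;
        }
      }
      cnt[c] = n;
      if (check_spacing) {
        for (int j = 1; j < n; ++j)
          if (p[j] - p[j - 1] < s_p) stop("spacing invariant violated");
      }
    }
  }

  // flatten final state
  int tot = 0;
  for (int c = 0; c < C; ++c) tot += cnt[c];
  IntegerVector out_cell(tot), out_pos(tot);
  int idx = 0;
  for (int c = 0; c < C; ++c) {
    const int *p = &pos[static_cast<size_t>(c) * maxp];
    for (int j = 0; j < cnt[c]; ++j) {
      out_cell[idx] = c + 1;
      out_pos[idx] = p[j];
      ++idx;
    }
  }
  return List::create(_["cell"] = out_cell, _["position"] = out_pos,
                      _["n_success"] = n_success, _["n_blocked"] = n_blocked);
}
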