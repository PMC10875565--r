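#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Per-replicate RNG stream: mt19937_64 keyed by (seed, replicate) only, so
// changing the replicate count never reshuffles earlier replicates.
static inline std::mt19937_64 make_stream(int seed, int rep) {
  std::seed_seq ss{static_cast<unsigned>(seed), static_cast<unsigned>(rep)};
  return std::mt19937_64(ss);
}

static inline double unif01(std::mt19937_64 &eng) {
  // 53-bit mantissa draw in [0, 1); deterministic across platforms
  return (eng() >> 11) * (1.0 / 9007199254740992.0);
}

struct StepCtx {
  int N;
  double w, a, c1, d1, c2, d2, dt;
};

// Both resource shares are carried explicitly (q1 + q2 = 1 up to
// rounding): the antisymmetric pair of share equations then stays exact
// under species relabelling, and each share keeps full relative
// floating-point precision near its own boundary. Folding q2 into
// 1 - q1 instead would make the y = 1 boundary absorbing ~2^-53 away
// while y = 0 stays resolvable down to the subnormal range, silently
// breaking label-swap symmetry on long trajectories.
static inline void resource_step_pair(double &q1, double &q2, int k,
                                      const StepCtx &m) {
  const double delta = m.a * q1 * q2 * (2.0 * k - m.N) * m.dt;
  q1 += delta;
  q2 -= delta;
  if (q1 < 0.0) q1 = 0.0; else if (q1 > 1.0) q1 = 1.0;
  if (q2 < 0.0) q2 = 0.0; else if (q2 > 1.0) q2 = 1.0;
}

// one birth-death event (fitnesses from the entry shares), then one
// Euler resource-share step using the post-update count
static inline void step_once(int &k, double &q1, double &q2,
                             const StepCtx &m, std::mt19937_64 &eng) {
  const double F1 = 1.0 - m.w + m.w * (m.c1 * q1 + m.d1);
  const double F2 = 1.0 - m.w + m.w * (m.c2 * q2 + m.d2);
  const double tot = k * F1 + (m.N - k) * F2;
  const double pup = k * F1 / tot * (double)(m.N - k) / m.N;
  const double pdn = (m.N - k) * F2 / tot * (double)k / m.N;
  const double u = unif01(eng);
  if (u < pup) ++k; else if (u < pup + pdn) --k;
  resource_step_pair(q1, q2, k, m);
}

// [[Rcpp::export]]
List cpp_simulate_batch(int N, double w, double a,
                        double c1, double d1, double c2, double d2,
                        double dt, int k0, double y0,
                        int n_reps, int seed, double max_steps) {
  IntegerVector winner(n_reps);
  NumericVector steps(n_reps), final_y1(n_reps);
  for (int r = 0; r < n_reps; ++r) {
    std::mt19937_64 eng = make_stream(seed, r + 1);
    StepCtx m{N, w, a, c1, d1, c2, d2, dt};
    int k = k0;
    double q1 = y0, q2 = 1.0 - y0;
    double t = 0.0;
    while (k > 0 && k < N && t < max_steps) {
      step_once(k, q1, q2, m, eng);
      t += 1.0;
    }
    winner[r] = (k == N) ? 1 : (k == 0 ? 2 : NA_INTEGER); // NA: not absorbed
    steps[r] = t;
    final_y1[r] = q1;
    if (r % 256 == 0) checkUserInterrupt();
  }
  return List::create(_["winner"] = winner, _["steps"] = steps,
                      _["final_y1"] = final_y1);
}

// [[Rcpp::export]]
NumericVector cpp_early_stage(int N, double w, double a,
                              double c1, double d1, double c2, double d2,
                              double dt, int k0, double y0,
                              int horizon, int n_reps, int seed) {
  std::vector<long> higher(horizon, 0L);
  for (int r = 0; r < n_reps; ++r) {
    std::mt19937_64 eng = make_stream(seed, r + 1);
    StepCtx m{N, w, a, c1, d1, c2, d2, dt};
    int k = k0;
    double q1 = y0, q2 = 1.0 - y0;
    for (int t = 0; t < horizon; ++t) {
      if (k > 0 && k < N) {
        step_once(k, q1, q2, m, eng);
      } else {
        // absorbed: the environment keeps evolving under the fixed counts
        resource_step_pair(q1, q2, k, m);
      }
      const double f1 = c1 * q1 + d1;
      const double f2 = c2 * q2 + d2;
      if (f1 > f2) ++higher[t]; // strict: ties are "not higher"
    }
    if (r % 256 == 0) checkUserInterrupt();
  }
  NumericVector out(horizon);
  for (int t = 0; t < horizon; ++t) out[t] = (double)higher[t] / n_reps;
  return out;
}
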