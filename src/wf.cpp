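#include <Rcpp.h>
#include <cstdint>
#include <random>

// Counter-based seeding: every (master seed, cell, replicate) triple gets its
// own RNG stream, so grid cells are independent and bit-reproducible without
// touching R's global RNG state.

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static std::mt19937_64 make_stream(uint64_t seed, uint64_t cell, uint64_t rep) {
  uint64_t s = splitmix64(seed);
  s = splitmix64(s ^ (cell * 0xA24BAED4963EE407ULL));
  s = splitmix64(s ^ (rep * 0x9FB21C651E98DF25ULL));
  return std::mt19937_64(s);
}

// Deterministic viability selection with genotype fitnesses
// (1+s, 1+h*s, 1), then binomial resampling of 2N alleles.
static inline double select_freq(double p, double s, double h) {
  double q = 1.0 - p;
  double wbar = p * p * (1.0 + s) + 2.0 * p * q * (1.0 + h * s) + q * q;
  return p * (p * (1.0 + s) + q * (1.0 + h * s)) / wbar;
}

struct WFParams {
  int total_gens, bn_dur, bn_size, exp_size, sel_start, sel_end;
  double s, h;
};

// One trajectory; writes the frequency path if `path` is non-null.
// Returns final frequency. Generation 0 holds p0 (before any selection or
// sampling); transition t (0-based) produces generation t+1 using the
// bottleneck size for the first bn_dur transitions.
static double run_traj(double p0, const WFParams &par, std::mt19937_64 &rng,
                       double *path) {
  double p = p0;
  if (path) path[0] = p;
  for (int t = 0; t < par.total_gens; ++t) {
    if (p > 0.0 && p < 1.0) {
      double pp = (t >= par.sel_start && t < par.sel_end) ? select_freq(p, par.s, par.h) : p;
      int N = (t < par.bn_dur) ? par.bn_size : par.exp_size;
      std::binomial_distribution<int> bin(2 * N, pp);
      p = static_cast<double>(bin(rng)) / (2.0 * N);
    }
    if (path) path[t + 1] = p;
  }
  return p;
}

// [[Rcpp::export(name = ".wf_trajectory_cpp")]]
Rcpp::NumericVector wf_trajectory_cpp(double p0, int total_gens, int bn_dur,
                                      int bn_size, int exp_size, double s,
                                      double h, int sel_start, int sel_end,
                                      double seed, double cell, double rep) {
  WFParams par{total_gens, bn_dur, bn_size, exp_size, sel_start, sel_end, s, h};
  Rcpp::NumericVector path(total_gens + 1);
  std::mt19937_64 rng = make_stream((uint64_t)seed, (uint64_t)cell, (uint64_t)rep);
  run_traj(p0, par, rng, path.begin());
  return path;
}

// [[Rcpp::export(name = ".wf_fix_count_cpp")]]
int wf_fix_count_cpp(double p0, int total_gens, int bn_dur, int bn_size,
                     int exp_size, double s, double h, int sel_start,
                     int sel_end, int replicates, double seed, double cell) {
  WFParams par{total_gens, bn_dur, bn_size, exp_size, sel_start, sel_end, s, h};
  int fixed = 0;
  for (int r = 0; r < replicates; ++r) {
    std::mt19937_64 rng = make_stream((uint64_t)seed, (uint64_t)cell, (uint64_t)r);
    if (run_traj(p0, par, rng, nullptr) >= 1.0) ++fixed;
  }
  return fixed;
}

// Vectorised grid evaluation: one row per cell, columns are the cell axes.
// cell index doubles as the stream selector so cells are independent.
// [[Rcpp::export(name = ".wf_grid_cpp")]]
Rcpp::NumericVector wf_grid_cpp(Rcpp::NumericVector p0, Rcpp::IntegerVector bn_size,
                                Rcpp::IntegerVector exp_size, Rcpp::IntegerVector sel_dur,
                                Rcpp::NumericVector s, int total_gens, int bn_dur,
                                double h, int replicates, double seed) {
  int n = p0.size();
  Rcpp::NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = (double)wf_fix_count_cpp(p0[i], total_gens, bn_dur, bn_size[i],
                                      exp_size[i], s[i], h, 0, sel_dur[i],
                                      replicates, seed, (double)(i + 1)) /
             replicates;
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
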