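// Serial-sampling coalescent simulator over piecewise-exponential epochs.
//
// Backward-time convention: an epoch starting at s with size N0 and rate r
// has haploid size N(t) = N0 * exp(r * (t - s)) for t in [s, next start).
// Lineages enter at their cohort sampling times; while k lineages are
// active the pairwise coalescence intensity is k(k-1)/2 / N(t), inverted
// in closed form through each epoch (no Euler stepping).
//
// The expected polymorphic SFS is estimated by accumulating each branch's
// length onto its (folded) entry across independent genealogies: under the
// infinite-sites model at low mutation rate, the probability that a random
// segregating site carries configuration e is E[l_e] / E[l_tot]. Every
// branch of every genealogy contributes; conditioning on polymorphism is
// automatic because every branch subtends a proper non-empty subset of the
// pooled sample.
//
// Two accumulation modes: a dense grid over all entries (full spectrum),
// and a support-restricted mode that tracks only the entries a composite-
// likelihood evaluation needs (plus the total length), which keeps the
// accumulator cache-resident during optimization.

#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

namespace {

// Fast natural log (bit-twiddled log2 with a degree-5 minimax polynomial
// on the mantissa): ~1e-9 relative accuracy, pure arithmetic so results
// are identical across platforms. Used for exponential waiting-time draws
// and their closed-form inversion, where Monte-Carlo noise dwarfs the
// approximation error.
inline double fast_log(double x) {
  union { double d; uint64_t i; } u = {x};
  int e = (int)((u.i >> 52) & 0x7ff) - 1023;
  u.i = (u.i & 0x000fffffffffffffULL) | 0x3ff0000000000000ULL;
  double m = u.d;  // in [1, 2)
  // minimax-style fit of ln(m) around m in [1, 2) via ln((1+t)/(1-t))
  double t = (m - 1.0) / (m + 1.0);
  double t2 = t * t;
  double lnm = 2.0 * t * (1.0 + t2 * (1.0 / 3.0 + t2 * (0.2 + t2 *
                (1.0 / 7.0 + t2 * (1.0 / 9.0 + t2 * (1.0 / 11.0))))));
  return lnm + e * 0.6931471805599453;
}

// xoshiro256++ (public-domain construction), seeded from R's RNG so that
// set.seed() governs reproducibility while avoiding per-draw R API calls.
struct FastRNG {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_R() {
    // splitmix64 over a 64-bit seed assembled from R's RNG stream
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32;
    seed ^= (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform in (0, 1)
  double runif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
  double rexp() { return -fast_log(runif()); }
  // uniform integer in [0, n)
  int rint(int n) { return (int)(runif() * n) % n; }
};

struct Epoch {
  double start;
  double size;     // haploid size at epoch start
  double rate;     // per-generation exponential rate (backward convention)
  double end;      // next epoch's start (Inf for the last)
  double exp_end;  // exp(-rate * (end - start)), 0 if end = Inf and rate > 0
};

struct Simulator {
  std::vector<Epoch> eps;
  std::vector<double> sample_times;   // sorted event times
  std::vector<int> sample_cohort;
  std::vector<int> sample_n;
  int ncoh, ntot;

  // per-run workspace
  std::vector<int> cnt;        // node counts per cohort
  std::vector<int64_t> node_idx;   // folded linear entry index per node
  std::vector<double> birth;
  std::vector<int> active;
  std::vector<int64_t> leaf_idx;   // folded entry index of a leaf, per cohort
  std::vector<int64_t> strides;
  std::vector<signed char> leafc;  // cohort of a leaf node, -1 for internal
  std::vector<double> leaf_len;    // per-cohort leaf branch length (per tree)
  // memo for exp(-r (t - s)) at a sampling-time boundary in one epoch
  int cache_j = -1;
  double cache_t = -1.0, cache_exp = 1.0;

  double exp_at(int j, double t) {
    if (j == cache_j && t == cache_t) return cache_exp;
    cache_j = j; cache_t = t;
    cache_exp = std::exp(-eps[j].rate * (t - eps[j].start));
    return cache_exp;
  }

  void init(NumericMatrix epochs, NumericVector times, IntegerVector sizes) {
    int n_ep = epochs.nrow();
    ncoh = times.size();
    eps.resize(n_ep);
    for (int j = 0; j < n_ep; ++j) {
      eps[j].start = epochs(j, 0);
      eps[j].size  = epochs(j, 1);
      eps[j].rate  = epochs(j, 2);
      if (eps[j].size <= 0) stop("epoch with non-positive size");
      eps[j].end = (j + 1 < n_ep) ? epochs(j + 1, 0) : R_PosInf;
      if (R_FINITE(eps[j].end))
        eps[j].exp_end = std::exp(-eps[j].rate * (eps[j].end - eps[j].start));
      else
        eps[j].exp_end = (eps[j].rate > 0) ? 0.0 : 1.0;  // unused if rate<=0
    }
    if (eps[n_ep - 1].rate != 0)
      stop("last (unbounded) epoch must have constant size");

    std::vector<int> ord(ncoh);
    for (int c = 0; c < ncoh; ++c) ord[c] = c;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return times[a] < times[b];
    });
    if (times[ord[0]] != 0.0)
      stop("at least one cohort must be sampled at time 0");
    ntot = 0;
    sample_times.clear(); sample_cohort.clear(); sample_n.clear();
    for (int c : ord) {
      if (sizes[c] < 0) stop("negative sample size");
      sample_times.push_back(times[c]);
      sample_cohort.push_back(c);
      sample_n.push_back(sizes[c]);
      ntot += sizes[c];
    }
    if (ntot < 2) stop("need at least 2 sampled haploids in total");

    strides.resize(ncoh);
    int64_t prod = 1;
    for (int c = 0; c < ncoh; ++c) {
      strides[c] = prod;
      prod *= (int64_t)(sizes[c] + 1);
    }
    // a single leaf is never on the majority side (ntot >= 2)
    leaf_idx.resize(ncoh);
    for (int c = 0; c < ncoh; ++c) leaf_idx[c] = strides[c];

    int max_nodes = 2 * ntot;
    cnt.assign((size_t)max_nodes * ncoh, 0);
    node_idx.assign(max_nodes, 0);
    birth.assign(max_nodes, 0.0);
    active.assign(ntot, 0);
    leafc.assign(max_nodes, -1);
    leaf_len.assign(ncoh, 0.0);
  }

  int64_t fold_index(const int* row, IntegerVector& sizes) {
    int pooled = 0;
    for (int c = 0; c < ncoh; ++c) pooled += row[c];
    int64_t idx = 0;
    if (2 * pooled > ntot) {
      for (int c = 0; c < ncoh; ++c) idx += (sizes[c] - row[c]) * strides[c];
    } else {
      for (int c = 0; c < ncoh; ++c) idx += row[c] * strides[c];
    }
    return idx;
  }

  // Simulate one genealogy, streaming each finished branch (entry index,
  // length) into the Sink. Sink::add(int64_t idx, double len).
  template <class Sink>
  void run(FastRNG& rng, IntegerVector& sizes, Sink& sink) {
    int n_nodes = 0, n_active = 0;
    size_t ev = 0;
    double t = 0.0;
    int j = 0;                    // current epoch
    double exp_cur = 1.0;         // exp(-r_j (t - s_j)) for the current epoch
    int remaining_pending = ntot;
    for (int c = 0; c < ncoh; ++c) leaf_len[c] = 0.0;
    auto add_branch = [&](int id, double len) {
      if (leafc[id] >= 0) leaf_len[leafc[id]] += len;
      else sink.add(node_idx[id], len);
    };

    while (n_active + remaining_pending > 1) {
      while (ev < sample_times.size() && sample_times[ev] <= t) {
        int c = sample_cohort[ev];
        for (int i = 0; i < sample_n[ev]; ++i) {
          int id = n_nodes++;
          int* row = &cnt[(size_t)id * ncoh];
          for (int c2 = 0; c2 < ncoh; ++c2) row[c2] = 0;
          row[c] = 1;
          node_idx[id] = leaf_idx[c];
          leafc[id] = (signed char)c;
          birth[id] = t;
          active[n_active++] = id;
        }
        remaining_pending -= sample_n[ev];
        ++ev;
      }
      double ts = (ev < sample_times.size()) ? sample_times[ev] : R_PosInf;
      if (n_active < 2) {
        t = ts;
        while (j + 1 < (int)eps.size() && eps[j + 1].start <= t) ++j;
        exp_cur = exp_at(j, t);
        continue;
      }
      double e = rng.rexp();
      double cc = 0.5 * n_active * (n_active - 1.0);
      double tcur = t, ecur = exp_cur;
      bool coalesced = false;
      while (true) {
        const Epoch& ep = eps[j];
        double seg_end = std::min(ep.end, ts);
        double inten, eend;
        if (ep.rate == 0.0) {
          inten = R_FINITE(seg_end) ? cc * (seg_end - tcur) / ep.size
                                    : R_PosInf;
          eend = 1.0;
        } else {
          eend = (seg_end == ep.end) ? ep.exp_end : exp_at(j, seg_end);
          if (!R_FINITE(seg_end) && ep.rate < 0) inten = R_PosInf;
          else inten = cc / (ep.size * ep.rate) * (ecur - eend);
        }
        if (e <= inten) {
          if (ep.rate == 0.0) {
            t = tcur + e * ep.size / cc;
          } else {
            ecur -= e * ep.rate * ep.size / cc;
            t = ep.start - fast_log(ecur) / ep.rate;
            exp_cur = ecur;
          }
          if (ep.rate == 0.0) exp_cur = 1.0;
          coalesced = true;
          break;
        }
        e -= inten;
        tcur = seg_end;
        ecur = eend;
        if (seg_end >= ts) break;    // sampling event interrupts the wait
        ++j;
        ecur = 1.0;                  // at the start of the next epoch
        if (j >= (int)eps.size()) stop("coalescent intensity exhausted");
      }
      if (!coalesced) {
        t = ts;
        while (j + 1 < (int)eps.size() && eps[j + 1].start <= t) ++j;
        exp_cur = exp_at(j, t);
        continue;
      }
      // merge two uniformly chosen active lineages at time t
      int ia = rng.rint(n_active);
      int ib = rng.rint(n_active - 1);
      if (ib >= ia) ++ib;
      int na = active[ia], nb = active[ib];
      add_branch(na, t - birth[na]);
      add_branch(nb, t - birth[nb]);
      int id = n_nodes++;
      int* row = &cnt[(size_t)id * ncoh];
      const int* ra = &cnt[(size_t)na * ncoh];
      const int* rb = &cnt[(size_t)nb * ncoh];
      for (int c2 = 0; c2 < ncoh; ++c2) row[c2] = ra[c2] + rb[c2];
      node_idx[id] = fold_index(row, sizes);
      leafc[id] = -1;
      birth[id] = t;
      int hi = std::max(ia, ib), lo = std::min(ia, ib);
      active[hi] = active[--n_active];
      active[lo] = active[n_active - 1];
      active[n_active - 1] = id;
    }
    // flush per-cohort leaf branch totals
    for (int c = 0; c < ncoh; ++c)
      if (leaf_len[c] > 0) sink.add(leaf_idx[c], leaf_len[c]);
  }
};

struct DenseSink {
  std::vector<double>& acc;
  void add(int64_t idx, double len) { acc[(size_t)idx] += len; }
};

// open-addressing lookup table: entry index -> slot in a small accumulator
struct SupportSink {
  std::vector<int64_t> keys;   // -1 = empty
  std::vector<int> slot;
  std::vector<double> acc;     // one accumulator per support entry
  double total = 0.0;
  uint64_t mask;

  void build(const NumericVector& support) {
    size_t cap = 16;
    while (cap < 4 * (size_t)support.size()) cap <<= 1;
    mask = cap - 1;
    keys.assign(cap, -1);
    slot.assign(cap, 0);
    acc.assign(support.size(), 0.0);
    for (int i = 0; i < support.size(); ++i) {
      int64_t key = (int64_t)support[i] - 1;   // 0-based
      uint64_t h = ((uint64_t)key * 0x9e3779b97f4a7c15ULL) & mask;
      while (keys[h] != -1) h = (h + 1) & mask;
      keys[h] = key;
      slot[h] = i;
    }
  }
  void add(int64_t idx, double len) {
    total += len;
    uint64_t h = ((uint64_t)idx * 0x9e3779b97f4a7c15ULL) & mask;
    while (true) {
      int64_t k = keys[h];
      if (k == idx) { acc[slot[h]] += len; return; }
      if (k == -1) return;
      h = (h + 1) & mask;
    }
  }
};

} // namespace

// Expected folded polymorphic multiSFS by branch-length accumulation.
// Returns sparse (index, weight): 1-based linear indices over the folded
// grid with dims sample_sizes + 1 (first cohort varying fastest) and
// normalized weights summing to 1.
// [[Rcpp::export(name = ".cpp_expected_folded_sfs")]]
List cpp_expected_folded_sfs(NumericMatrix epochs,
                             NumericVector sample_times,
                             IntegerVector sample_sizes,
                             int n_sims) {
  if (n_sims < 1) stop("n_sims must be >= 1");
  Simulator sim;
  sim.init(epochs, sample_times, sample_sizes);
  double prod = 1.0;
  for (int c = 0; c < sample_sizes.size(); ++c) prod *= sample_sizes[c] + 1.0;
  if (prod > 2e8) stop("entry grid too large for dense accumulation");
  std::vector<double> acc((size_t)prod, 0.0);
  DenseSink sink{acc};
  RNGScope scope;
  FastRNG rng;
  rng.seed_from_R();
  for (int s = 0; s < n_sims; ++s) sim.run(rng, sample_sizes, sink);

  double total = 0.0;
  size_t nz = 0;
  for (double v : acc) if (v > 0) { total += v; ++nz; }
  NumericVector idx_out(nz), w_out(nz);
  size_t k = 0;
  for (size_t i = 0; i < acc.size(); ++i) {
    if (acc[i] > 0) {
      idx_out[k] = (double)(i + 1);
      w_out[k] = acc[i] / total;
      ++k;
    }
  }
  return List::create(_["index"] = idx_out, _["weight"] = w_out);
}

// Expected probabilities restricted to a set of entry indices (1-based
// linear indices on the folded grid). Returns weights len_e / len_total,
// i.e. the same estimator as the dense path evaluated at the support
// (entries outside the support contribute to the normalizer only).
// The first row of the result uses all n_sims genealogies; the second row
// uses only the first half of the stream, which supports Richardson
// extrapolation of plug-in functionals such as the composite
// log-likelihood (their Monte-Carlo bias is O(1/n_sims)).
// [[Rcpp::export(name = ".cpp_expected_probs_at")]]
NumericMatrix cpp_expected_probs_at(NumericMatrix epochs,
                                    NumericVector sample_times,
                                    IntegerVector sample_sizes,
                                    int n_sims,
                                    NumericVector support) {
  if (n_sims < 1) stop("n_sims must be >= 1");
  Simulator sim;
  sim.init(epochs, sample_times, sample_sizes);
  SupportSink sink;
  sink.build(support);
  RNGScope scope;
  FastRNG rng;
  rng.seed_from_R();
  int half = n_sims / 2;
  std::vector<double> acc_half;
  double total_half = 0.0;
  for (int s = 0; s < n_sims; ++s) {
    if (s == half && half >= 1) {
      acc_half = sink.acc;
      total_half = sink.total;
    }
    sim.run(rng, sample_sizes, sink);
  }
  if (half < 1) { acc_half = sink.acc; total_half = sink.total; }
  NumericMatrix out(2, support.size());
  for (int i = 0; i < support.size(); ++i) {
    out(0, i) = sink.acc[i] / sink.total;
    out(1, i) = acc_half[i] / total_half;
  }
  return out;
}
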