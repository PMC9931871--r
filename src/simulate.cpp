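// Monte-Carlo core for House-of-Cards accessibility on Cartesian power
// genotype spaces.
//
// Genotypes are mixed-radix integers over the allele alphabet, locus 0 least
// significant. Accessibility of b from a is decided by a single pass over
// genotypes sorted by fitness: processing in increasing fitness order and
// propagating reachability along in-arrows guarantees that every marked
// predecessor has strictly lower fitness (ties are a measure-zero event and
// fall back to index order through the sort). A witness path is recovered
// from predecessor pointers and is automatically simple because fitness
// increases strictly along it.
//
// Randomness is a counter-based splitmix64 stream seeded per replicate from
// (master seed, replicate index), so replicates are order-independent and
// fitness draws are identical across beta values (common-random-numbers
// coupling).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

namespace {

struct SplitMix64 {
  uint64_t state;
  explicit SplitMix64(uint64_t seed) : state(seed) {}
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  // uniform double in (0, 1)
  double unif() { return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0); }
};

struct ProductSpace {
  int n;                                  // alleles
  int L;                                  // loci
  long G;                                 // genotype count n^L
  std::vector<long> pow;                  // n^l
  std::vector<std::vector<int>> in_nbrs;  // per allele: in-neighbours
  ProductSpace(const IntegerMatrix& adj, int L_) : n(adj.nrow()), L(L_) {
    G = 1;
    pow.resize(L);
    for (int l = 0; l < L; ++l) {
      pow[l] = G;
      G *= n;
    }
    in_nbrs.resize(n);
    for (int w = 0; w < n; ++w)
      for (int v = 0; v < n; ++v)
        if (adj(v, w) != 0) in_nbrs[w].push_back(v);
  }
};

// Single-landscape accessibility sweep. fitness has length G; returns the
// witness length (>= 1) if b is reachable from a along strictly increasing
// fitness, or -1. If path_out is non-null, fills it with the witness
// genotype ids (a .. b).
int accessibility_sweep(const ProductSpace& ps, const std::vector<double>& F,
                        long a_id, long b_id, std::vector<long>* path_out,
                        std::vector<long>& order, std::vector<long>& pred) {
  const long G = ps.G;
  order.resize(G);
  for (long g = 0; g < G; ++g) order[g] = g;
  std::sort(order.begin(), order.end(),
            [&F](long i, long j) { return F[i] < F[j] || (F[i] == F[j] && i < j); });
  pred.assign(G, -2); // -2 unreached, -1 source
  pred[a_id] = -1;
  const double Fb = F[b_id];
  for (long k = 0; k < G; ++k) {
    long g = order[k];
    if (F[g] > Fb) break; // nothing above b's fitness can matter
    if (g == a_id) continue;
    // decode digits and scan in-neighbours on each locus
    long rest = g;
    for (int l = 0; l < ps.L && pred[g] == -2; ++l) {
      int d = static_cast<int>((g / ps.pow[l]) % ps.n);
      for (int c : ps.in_nbrs[d]) {
        long h = g + static_cast<long>(c - d) * ps.pow[l];
        if (pred[h] != -2 && F[h] < F[g]) {
          pred[g] = h;
          break;
        }
      }
    }
    (void)rest;
    if (g == b_id) break;
  }
  if (pred[b_id] == -2) return -1;
  int len = 0;
  long cur = b_id;
  if (path_out) path_out->clear();
  while (cur != a_id) {
    if (path_out) path_out->push_back(cur);
    cur = pred[cur];
    ++len;
  }
  if (path_out) {
    path_out->push_back(a_id);
    std::reverse(path_out->begin(), path_out->end());
  }
  return len;
}

} // namespace

// [[Rcpp::export]]
List check_accessible_cpp(IntegerMatrix adj, int L, NumericVector fitness,
                          double a_id1, double b_id1) {
  ProductSpace ps(adj, L);
  if (static_cast<long>(fitness.size()) != ps.G)
    stop("fitness vector has wrong length");
  std::vector<double> F(fitness.begin(), fitness.end());
  std::vector<long> order, pred, path;
  long a_id = static_cast<long>(a_id1) - 1;
  long b_id = static_cast<long>(b_id1) - 1;
  int len = accessibility_sweep(ps, F, a_id, b_id, &path, order, pred);
  if (len < 0) return List::create(_["accessible"] = false,
                                   _["path"] = IntegerVector(0));
  IntegerVector p(path.size());
  for (size_t i = 0; i < path.size(); ++i) p[i] = static_cast<int>(path[i]) + 1;
  return List::create(_["accessible"] = true, _["path"] = p);
}

// method: 0 = conditioned-uniform (F[a]=0, F[b]=beta, interior U(0,1));
//         1 = Bernoulli(beta) site thinning + rank-only accessibility.
// Returns per-replicate witness lengths (-1 when inaccessible).
// [[Rcpp::export]]
IntegerVector simulate_accessibility_cpp(IntegerMatrix adj, int L,
                                         double a_id1, double b_id1,
                                         double beta, int reps,
                                         double seed, int method) {
  ProductSpace ps(adj, L);
  long a_id = static_cast<long>(a_id1) - 1;
  long b_id = static_cast<long>(b_id1) - 1;
  const long G = ps.G;
  IntegerVector out(reps);
  std::vector<double> F(G);
  std::vector<long> order, pred;
  const uint64_t master = static_cast<uint64_t>(seed);
  for (int rep = 0; rep < reps; ++rep) {
    // per-replicate stream: mix the master seed with the replicate index
    SplitMix64 rng(master * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL +
                   static_cast<uint64_t>(rep));
    if (method == 0) {
      for (long g = 0; g < G; ++g) F[g] = rng.unif();
      F[a_id] = 0.0;
      F[b_id] = beta;
    } else {
      // thinning: vertex survives w.p. beta, then only ranks matter
      for (long g = 0; g < G; ++g) {
        double keep = rng.unif();
        double rank = rng.unif();
        F[g] = (keep < beta) ? rank : 2.0; // 2.0: excluded (above b)
      }
      F[a_id] = -1.0;
      F[b_id] = 1.5;
    }
    out[rep] = accessibility_sweep(ps, F, a_id, b_id, nullptr, order, pred);
    if (rep % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
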