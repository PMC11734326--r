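#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// splitmix64: fast, well-mixed 64-bit finalizer. The sketch keeps only the
// low 53 bits of each hash so values stay exact when handed to R as doubles.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static const uint64_t HASH_SEED = 0x4D617368ULL;        // fixed seed constant
static const uint64_t MASK53  = (1ULL << 53) - 1;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Hashes of distinct canonical k-mers of one sequence. K-mers are packed
// 2 bits per base (A<C<G<T matches lexicographic order, so the numeric
// minimum of forward and reverse-complement encodings is the canonical
// k-mer). Windows containing non-ACGT characters are skipped and counted.
// [[Rcpp::export(name = ".kmer_hashes")]]
List kmer_hashes(std::string seq, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  size_t n = seq.size();
  if (n < (size_t)k) stop("sequence shorter than k");

  uint64_t fwd = 0, rev = 0;
  const int shift = 2 * (k - 1);
  const uint64_t kmask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int filled = 0;                   // valid bases in current window
  long long skipped = 0;            // k-mer windows lost to non-ACGT bases
  std::unordered_set<uint64_t> seen;
  seen.reserve(n);

  for (size_t i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) {                    // invalidates every window spanning it
      filled = 0; fwd = 0; rev = 0;
      continue;
    }
    fwd = ((fwd << 2) | (uint64_t)c) & kmask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++filled >= k) {
      uint64_t canon = std::min(fwd, rev);
      seen.insert(splitmix64(canon ^ HASH_SEED) & MASK53);
    }
  }
  // recount skipped windows simply: total windows minus valid ones
  long long total_windows = (long long)(n - k + 1);
  long long valid = 0;
  {
    int run = 0;
    for (size_t i = 0; i < n; ++i) {
      if (base_code(seq[i]) >= 0) { if (++run >= k) ++valid; }
      else run = 0;
    }
  }
  skipped = total_windows - valid;

  std::vector<double> out(seen.begin(), seen.end());
  std::sort(out.begin(), out.end());
  return List::create(_["hashes"] = NumericVector(out.begin(), out.end()),
                      _["n_kmers"] = (double)valid,
                      _["n_skipped"] = (double)skipped);
}

// Shared-hash count among the bottom-s distinct hashes of the union of two
// sorted hash vectors (the Mash estimator of Jaccard similarity).
// [[Rcpp::export(name = ".sketch_shared")]]
List sketch_shared(NumericVector a, NumericVector b, int s) {
  size_t i = 0, j = 0;
  int taken = 0, shared = 0;
  while (taken < s && (i < (size_t)a.size() || j < (size_t)b.size())) {
    if (j >= (size_t)b.size() || (i < (size_t)a.size() && a[i] < b[j])) {
      ++i; ++taken;
    } else if (i >= (size_t)a.size() || b[j] < a[i]) {
      ++j; ++taken;
    } else {
      ++i; ++j; ++taken; ++shared;
    }
  }
  return List::create(_["shared"] = shared, _["union_size"] = taken);
}
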