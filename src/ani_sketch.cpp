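#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// SplitMix64 finaliser: well-mixed 64-bit hash of a 64-bit key.
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // ambiguity: resets the k-mer window
  }
}

// Bottom-s MinHash sketch over canonical k-mers of one or more contigs.
// Canonical form = min(forward 2-bit code, reverse-complement code); k-mers
// containing ambiguous bases are skipped. Hashes are seeded, deduplicated,
// and returned as the smallest `sketch_size` values scaled into 53 bits so
// they remain exact in an R double.
// [[Rcpp::export]]
NumericVector sketch_minhash(CharacterVector seqs, int k, int sketch_size,
                             double seed) {
  if (k < 4 || k > 32) stop("k must be in [4, 32]");
  if (sketch_size < 1) stop("sketch_size must be >= 1");
  const uint64_t seed_mix = splitmix64((uint64_t)seed);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  std::vector<uint64_t> hashes;
  for (int s = 0; s < seqs.size(); ++s) {
    const char *str = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rev = 0;
    int run = 0;
    for (const char *p = str; *p; ++p) {
      int c = base_code(*p);
      if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++run >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(splitmix64(canon ^ seed_mix));
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  size_t n = std::min((size_t)sketch_size, hashes.size());
  NumericVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = (double)(hashes[i] >> 11);
  return out;
}
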