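#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// splitmix64 finalizer; decorrelates lexicographically adjacent k-mer codes
static inline uint64_t mix64(uint64_t x) {
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
    default: return -1;
  }
}

//' Hashed canonical k-mer set of a genome
//'
//' Computes the set of canonical k-mers (lexicographic minimum of a k-mer and
//' its reverse complement, on the 2-bit code) over all contigs, hashes each
//' with a 64-bit mixer, and returns the sorted unique hash values truncated to
//' 53 bits so they are exactly representable as doubles. k-mers spanning
//' non-ACGT characters are skipped; k-mers never span contig boundaries.
//'
//' @param contigs character vector of contig sequences
//' @param k k-mer size (1..31)
//' @return sorted numeric vector of distinct k-mer hash values
//' @keywords internal
// [[Rcpp::export]]
NumericVector kmer_hash_set(CharacterVector contigs, int k) {
  if (k < 1 || k > 31) stop("k must be in 1..31");
  std::vector<uint64_t> hashes;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (R_xlen_t ci = 0; ci < contigs.size(); ++ci) {
    const char *s = CHAR(STRING_ELT(contigs, ci));
    R_xlen_t n = LENGTH(STRING_ELT(contigs, ci));
    if (n < k) continue;
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid >= k) {
        uint64_t canon = fwd < rev ? fwd : rev;
        hashes.push_back(mix64(canon) >> 11); // keep 53 high bits
      }
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
  return out;
}

//' Size of the intersection of two sorted numeric vectors
//' @keywords internal
// [[Rcpp::export]]
double sorted_intersect_size(NumericVector a, NumericVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
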