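#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
using namespace Rcpp;

// 2-bit packed kmer codes stored in doubles: k <= 26 keeps 2k bits < 2^53,
// so every code is exactly representable and ordinary numeric comparison
// agrees with lexicographic order on A<C<G<T.

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or anything else invalidates the window
  }
}

// [[Rcpp::export(name = ".kmer_codes")]]
NumericVector kmer_codes(std::string seq, int k, bool canonical) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  const long n = (long) seq.size();
  std::vector<uint64_t> out;
  if (n < k) return NumericVector(0);
  out.reserve(n - k + 1);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int valid = 0; // consecutive valid bases ending at current position
  for (long i = 0; i < n; ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rev = (rev >> 2) | (((uint64_t) (3 - b)) << shift);
    if (++valid >= k) {
      uint64_t code = fwd;
      if (canonical && rev < fwd) code = rev;
      out.push_back(code);
    }
  }
  std::sort(out.begin(), out.end());
  out.erase(std::unique(out.begin(), out.end()), out.end());
  NumericVector res(out.size());
  for (size_t i = 0; i < out.size(); ++i) res[i] = (double) out[i];
  return res;
}

// [[Rcpp::export(name = ".decode_kmers")]]
CharacterVector decode_kmers(NumericVector codes, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  CharacterVector res(codes.size());
  std::string buf(k, 'A');
  for (R_xlen_t i = 0; i < codes.size(); ++i) {
    uint64_t code = (uint64_t) codes[i];
    for (int j = k - 1; j >= 0; --j) {
      buf[j] = bases[code & 3ULL];
      code >>= 2;
    }
    res[i] = buf;
  }
  return res;
}

// Number of elements of sorted vector x found in sorted vector table.
// [[Rcpp::export(name = ".count_in_sorted")]]
double count_in_sorted(NumericVector x, NumericVector table) {
  double n = 0;
  R_xlen_t i = 0, j = 0;
  while (i < x.size() && j < table.size()) {
    if (x[i] < table[j]) ++i;
    else if (x[i] > table[j]) ++j;
    else { ++n; ++i; ++j; }
  }
  return n;
}
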