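#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// 64-bit mix (splitmix64 finalizer); deterministic across platforms.
static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
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

// Bottom sketch of canonical k-mer hashes. sketch_size = 0 keeps every
// distinct hash (exact k-mer set, for Jaccard oracles). Hashes are
// truncated to 53 bits so they survive the round trip through doubles.
// Windows containing non-ACGT characters are skipped.
// [[Rcpp::export(name = ".kmer_sketch_cpp")]]
NumericVector kmer_sketch_cpp(std::string seq, int k, int sketch_size,
                              double seed) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  const uint64_t useed = (uint64_t)seed;
  const int n = (int)seq.size();
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<uint64_t> hashes;
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      uint64_t canon = std::min(fwd, rev);
      hashes.push_back(mix64(canon ^ useed) >> 11);
    }
  }
  std::sort(hashes.begin(), hashes.end());
  hashes.erase(std::unique(hashes.begin(), hashes.end()), hashes.end());
  if (sketch_size > 0 && (int)hashes.size() > sketch_size)
    hashes.resize(sketch_size);
  NumericVector out(hashes.size());
  for (size_t i = 0; i < hashes.size(); ++i) out[i] = (double)hashes[i];
  return out;
}

// IUPAC bitmasks: A=1 C=2 G=4 T=8. A sequence 'N' carries only bit 16 so
// it is matched by a consensus 'N' (mask 31) but by no specific base, and
// non-IUPAC separator characters (mask 0) match nothing at all.
static inline int seq_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'N': case 'n': return 16;
    default: return 0;
  }
}

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'R': case 'r': return 1 | 4;
    case 'Y': case 'y': return 2 | 8;
    case 'S': case 's': return 2 | 4;
    case 'W': case 'w': return 1 | 8;
    case 'K': case 'k': return 4 | 8;
    case 'M': case 'm': return 1 | 2;
    case 'B': case 'b': return 2 | 4 | 8;
    case 'D': case 'd': return 1 | 4 | 8;
    case 'H': case 'h': return 1 | 2 | 8;
    case 'V': case 'v': return 1 | 2 | 4;
    case 'N': case 'n': return 1 | 2 | 4 | 8 | 16;
    default: return -1;
  }
}

// Sliding Hamming scan of a (possibly degenerate, case-folded) consensus.
// Reports every 0-based start whose window has <= max_mm mismatching
// columns; early exit once the budget is exceeded.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
List hamming_scan_cpp(std::string seq, std::string consensus, int max_mm) {
  const int n = (int)seq.size();
  const int m = (int)consensus.size();
  std::vector<int> cmask(m);
  for (int j = 0; j < m; ++j) {
    int mk = iupac_mask(consensus[j]);
    if (mk < 0) stop("non-IUPAC character in consensus");
    cmask[j] = mk;
  }
  std::vector<int> smask(n);
  for (int i = 0; i < n; ++i) smask[i] = seq_mask(seq[i]);
  std::vector<int> starts, mms;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if ((smask[i + j] & cmask[j]) == 0 && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { starts.push_back(i); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}

// For every L-window of `text`, the number of L-windows (itself included)
// within Hamming distance max_mm. Windows containing non-ACGT characters
// are invalid seeds (count 0) and mismatch wherever compared. Used as a
// pre-screen so repeat discovery only refines seeds that can reach the
// copy-number floor.
// [[Rcpp::export(name = ".seed_count_cpp")]]
IntegerVector seed_count_cpp(std::string text, int L, int max_mm) {
  const int n = (int)text.size();
  const int P = n - L + 1;
  if (P <= 0) return IntegerVector(0);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(text[i]);
  std::vector<bool> valid(P);
  for (int i = 0; i < P; ++i) {
    bool ok = true;
    for (int k = 0; k < L; ++k)
      if (code[i + k] < 0) { ok = false; break; }
    valid[i] = ok;
  }
  IntegerVector counts(P);
  for (int i = 0; i < P; ++i) {
    if (!valid[i]) { counts[i] = 0; continue; }
    int c = 0;
    for (int j = 0; j < P; ++j) {
      int mm = 0;
      for (int k = 0; k < L; ++k) {
        int a = code[i + k], b = code[j + k];
        if (a != b || b < 0) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) ++c;
    }
    counts[i] = c;
  }
  return counts;
}

// Inverted-repeat scan: windows arm + spacer + revcomp(arm); mismatches
// counted over arm columns only (the spacer is free). Non-ACGT characters
// in either arm count as mismatches.
// [[Rcpp::export(name = ".inverted_scan_cpp")]]
List inverted_scan_cpp(std::string seq, int arm, int spacer, int max_mm) {
  const int n = (int)seq.size();
  const int w = 2 * arm + spacer;
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  std::vector<int> starts, mms;
  for (int i = 0; i + w <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < arm; ++j) {
      int a = code[i + j];
      int b = code[i + w - 1 - j];
      if (a < 0 || b < 0 || a != 3 - b) {
        if (++mm > max_mm) break;
      }
    }
    if (mm <= max_mm) { starts.push_back(i); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}
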