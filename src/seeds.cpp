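#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// Spaced-seed keys and minimizer subsampling. Keys are a 64-bit multiply-mix
// over the residues at the care positions, truncated to 53 bits so they are
// exactly representable as R doubles. Constants fixed for cross-platform
// determinism.

namespace {

const uint64_t MIX1 = 0x9E3779B97F4A7C15ULL;
const uint64_t MIX2 = 0xC2B2AE3D27D4EB4FULL;
const uint64_t MASK53 = (1ULL << 53) - 1;

inline int residue_code(char c) {
  // A..Z -> 0..25; anything else treated as 'X'
  if (c >= 'A' && c <= 'Z') return c - 'A';
  return 'X' - 'A';
}

inline uint64_t finalize(uint64_t h) {
  h ^= h >> 33; h *= MIX2; h ^= h >> 29;
  return h & MASK53;
}

// keys[p] for window starting at 0-based position p; n = L - span + 1
std::vector<double> window_keys(const std::string& s,
                                const std::vector<int>& care, int span) {
  const int L = (int)s.size();
  const int n = L - span + 1;
  std::vector<double> keys;
  if (n <= 0) return keys;
  keys.resize(n);
  for (int p = 0; p < n; ++p) {
    uint64_t h = 0;
    for (int c : care) h = (h ^ (uint64_t)residue_code(s[p + c])) * MIX1;
    keys[p] = (double)finalize(h);
  }
  return keys;
}

std::vector<int> care_positions(const LogicalVector& pattern) {
  std::vector<int> care;
  for (int k = 0; k < pattern.size(); ++k)
    if (pattern[k]) care.push_back(k);
  return care;
}

} // namespace

// [[Rcpp::export]]
DataFrame cc_seed_keys(std::string seq, LogicalVector pattern) {
  std::vector<int> care = care_positions(pattern);
  std::vector<double> keys = window_keys(seq, care, pattern.size());
  IntegerVector pos((int)keys.size());
  for (int p = 0; p < (int)keys.size(); ++p) pos[p] = p + 1; // 1-based start
  return DataFrame::create(_["pos"] = pos, _["key"] = NumericVector(keys.begin(), keys.end()));
}

// [[Rcpp::export]]
DataFrame cc_minimizers(std::string seq, LogicalVector pattern, int w) {
  std::vector<int> care = care_positions(pattern);
  std::vector<double> keys = window_keys(seq, care, pattern.size());
  const int n = (int)keys.size();
  std::vector<int> picked;
  if (n > 0 && n < w) {
    // short sequence: emit the single minimal seed over available positions
    int arg = 0;
    for (int p = 1; p < n; ++p) if (keys[p] < keys[arg]) arg = p;
    picked.push_back(arg);
  } else if (n >= w) {
    int last = -1;
    for (int s = 0; s + w <= n; ++s) {
      int arg = s;
      for (int p = s + 1; p < s + w; ++p)
        if (keys[p] < keys[arg]) arg = p; // ties -> leftmost
      if (arg != last) { picked.push_back(arg); last = arg; }
    }
  }
  IntegerVector pos((int)picked.size());
  NumericVector key((int)picked.size());
  for (int k = 0; k < (int)picked.size(); ++k) {
    pos[k] = picked[k] + 1;
    key[k] = keys[picked[k]];
  }
  return DataFrame::create(_["pos"] = pos, _["key"] = key);
}

// alignment column codes: 1 = identical aligned pair, 0 = mismatch, 2 = gap
// [[Rcpp::export]]
LogicalMatrix cc_shape_hits(List aln_codes, List shape_masks) {
  const int na = aln_codes.size(), ns = shape_masks.size();
  LogicalMatrix hits(na, ns);
  std::vector<std::vector<int>> cares(ns);
  std::vector<int> spans(ns);
  for (int s = 0; s < ns; ++s) {
    LogicalVector m = shape_masks[s];
    spans[s] = m.size();
    for (int k = 0; k < m.size(); ++k)
      if (m[k]) cares[s].push_back(k);
  }
  for (int a = 0; a < na; ++a) {
    IntegerVector cols = aln_codes[a];
    const int L = cols.size();
    // next gap position at or after each column (for gap-free window test)
    std::vector<int> next_gap(L + 1, L);
    for (int p = L - 1; p >= 0; --p)
      next_gap[p] = (cols[p] == 2) ? p : next_gap[p + 1];
    for (int s = 0; s < ns; ++s) {
      const int span = spans[s];
      bool hit = false;
      for (int o = 0; o + span <= L && !hit; ++o) {
        if (next_gap[o] < o + span) continue; // window contains a gap column
        bool ok = true;
        for (int c : cares[s])
          if (cols[o + c] != 1) { ok = false; break; }
        hit = ok;
      }
      hits(a, s) = hit;
    }
  }
  return hits;
}
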