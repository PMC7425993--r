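#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding; A<C<G<T preserves lexicographic order, so the numeric
// minimum of (forward, reverse-complement) codes coincides with the
// lexicographic canonical k-mer.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    char c = s[s.size() - 1 - i];
    switch (c) {
    case 'A': out[i] = 'T'; break;
    case 'C': out[i] = 'G'; break;
    case 'G': out[i] = 'C'; break;
    case 'T': out[i] = 'A'; break;
    case 'a': out[i] = 't'; break;
    case 'c': out[i] = 'g'; break;
    case 'g': out[i] = 'c'; break;
    case 't': out[i] = 'a'; break;
    default: out[i] = 'N';
    }
  }
  return out;
}

static bool encode_kmer(const std::string& s, uint64_t& code) {
  code = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bit(s[i]);
    if (b < 0) return false;
    code = (code << 2) | (uint64_t)b;
  }
  return true;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp_str(as<std::string>(x[i]));
  return out;
}

// Count canonical occurrences of panel k-mers across reads (both strands,
// N-containing windows skipped). Counts aligned to the input k-mer order.
// [[Rcpp::export]]
IntegerVector cpp_count_kmers(CharacterVector reads, CharacterVector kmers, int k) {
  if (k < 1 || k > 31) stop("k must be between 1 and 31");
  std::unordered_map<uint64_t, int> idx;
  idx.reserve(kmers.size() * 2);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int)km.size() != k) stop("panel k-mer of wrong length");
    uint64_t f, r;
    if (!encode_kmer(km, f)) stop("panel k-mer contains non-ACGT base");
    encode_kmer(revcomp_str(km), r);
    idx[std::min(f, r)] = (int)i;
  }
  IntegerVector counts(kmers.size(), 0);
  const uint64_t mask = (k == 31) ? ~0ULL >> 2 : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    const char* s = CHAR(STRING_ELT(reads, ri));
    int n = (int)LENGTH(STRING_ELT(reads, ri));
    uint64_t f = 0, r = 0;
    int run = 0;
    for (int j = 0; j < n; ++j) {
      int b = base2bit(s[j]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        uint64_t canon = std::min(f, r);
        auto it = idx.find(canon);
        if (it != idx.end()) counts[it->second]++;
      }
    }
  }
  return counts;
}

// Semi-global edit distance: the pattern is aligned end to end, read (text)
// ends are free. Levenshtein costs. maxed >= 0 enables row-minimum early
// abort (returns maxed + 1 when the bound is exceeded); maxed < 0 is exact.
static int edit_semiglobal(const std::string& p, const std::string& t, int maxed) {
  int m = (int)p.size(), n = (int)t.size();
  if (m == 0) return 0;
  std::vector<int> prev(n + 1, 0), cur(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    cur[0] = i;
    int rowmin = cur[0];
    const char pc = p[i - 1];
    for (int j = 1; j <= n; ++j) {
      int cost = (pc == t[j - 1]) ? 0 : 1;
      int v = prev[j - 1] + cost;
      if (prev[j] + 1 < v) v = prev[j] + 1;
      if (cur[j - 1] + 1 < v) v = cur[j - 1] + 1;
      cur[j] = v;
      if (v < rowmin) rowmin = v;
    }
    if (maxed >= 0 && rowmin > maxed) return maxed + 1;
    std::swap(prev, cur);
  }
  return *std::min_element(prev.begin(), prev.end());
}

// Pigeonhole seed filter: if edit(p in t) <= maxed then at least one of the
// maxed + 1 contiguous pattern segments occurs exactly in t.
static bool seed_hit(const std::string& t, const std::string& p, int maxed) {
  int nseg = maxed + 1;
  size_t m = p.size();
  if (m == 0) return true;
  for (int i = 0; i < nseg; ++i) {
    size_t a = (m * i) / nseg, b = (m * (i + 1)) / nseg;
    if (b <= a) continue;
    if (t.find(p.substr(a, b - a)) != std::string::npos) return true;
  }
  return false;
}

static bool matches_either_strand(const std::string& s, const std::string& rc,
                                  const std::string& p, int maxed) {
  if (seed_hit(s, p, maxed) && edit_semiglobal(p, s, maxed) <= maxed) return true;
  if (seed_hit(rc, p, maxed) && edit_semiglobal(p, rc, maxed) <= maxed) return true;
  return false;
}

// [[Rcpp::export]]
int cpp_edit_semiglobal(std::string pattern, std::string text) {
  return edit_semiglobal(pattern, text, -1);
}

// Minimum Hamming distance of pattern over all gap-free placements in text
// (substitution-only mode); returns pattern length + 1 if pattern is longer
// than text.
// [[Rcpp::export]]
int cpp_hamming_min(std::string pattern, std::string text) {
  int m = (int)pattern.size(), n = (int)text.size();
  if (m > n) return m + 1;
  int best = m + 1;
  for (int s = 0; s + m <= n; ++s) {
    int d = 0;
    for (int i = 0; i < m && d < best; ++i)
      if (pattern[i] != text[s + i]) ++d;
    if (d < best) best = d;
  }
  return best;
}

// Bulk spanning-read caller. full_patterns[c-1] is the full-span pattern for
// c copies (left anchor + c units + right anchor). pl/pr are the open-class
// partial patterns (unit fragment + C_max units, resp. C_max units + unit
// fragment); plf/prf the corresponding flank-explained alternatives.
// Returns per read: 0 = no evidence, c = full span, open_label = partial
// (> C_max) evidence, -1 = ambiguous full-span match (should not occur).
// [[Rcpp::export]]
IntegerVector cpp_call_reads(CharacterVector reads, CharacterVector full_patterns,
                             std::string pl, std::string plf,
                             std::string pr, std::string prf,
                             int max_edit, int open_label) {
  int npat = (int)full_patterns.size();
  std::vector<std::string> pats(npat);
  for (int c = 0; c < npat; ++c) pats[c] = as<std::string>(full_patterns[c]);
  IntegerVector out(reads.size(), 0);
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    std::string rc = revcomp_str(s);
    int nmatch = 0, match_c = 0;
    for (int c = 0; c < npat; ++c) {
      if (matches_either_strand(s, rc, pats[c], max_edit)) {
        ++nmatch;
        match_c = c + 1;
      }
    }
    if (nmatch == 1) { out[i] = match_c; continue; }
    if (nmatch > 1) { out[i] = -1; continue; }
    bool left = matches_either_strand(s, rc, pl, max_edit) &&
                !matches_either_strand(s, rc, plf, max_edit);
    bool right = !left && matches_either_strand(s, rc, pr, max_edit) &&
                 !matches_either_strand(s, rc, prf, max_edit);
    if (left || right) out[i] = open_label;
  }
  return out;
}

// Scan for reads consistent with >= n_units + 2 repeat copies: pb is the
// combined pattern (unit fragment + n_units units + unit fragment); pbl/pbr
// replace one partial fragment by flank sequence (flank-explained guards).
// [[Rcpp::export]]
LogicalVector cpp_scan_six(CharacterVector reads, std::string pb,
                           std::string pbl, std::string pbr, int max_edit) {
  LogicalVector out(reads.size());
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    std::string rc = revcomp_str(s);
    out[i] = matches_either_strand(s, rc, pb, max_edit) &&
             !matches_either_strand(s, rc, pbl, max_edit) &&
             !matches_either_strand(s, rc, pbr, max_edit);
  }
  return out;
}
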