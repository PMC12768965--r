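#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <algorithm>
using namespace Rcpp;

// Codon helpers ------------------------------------------------------------

static inline bool is_stop(const char *c) {
  // TAA, TAG, TGA
  if (c[0] != 'T') return false;
  if (c[1] == 'A' && (c[2] == 'A' || c[2] == 'G')) return true;
  if (c[1] == 'G' && c[2] == 'A') return true;
  return false;
}

static inline bool is_start(const char *c) {
  // ATG, GTG, TTG
  return c[1] == 'T' && c[2] == 'G' &&
         (c[0] == 'A' || c[0] == 'G' || c[0] == 'T');
}

static inline bool has_ambig(const char *c) {
  for (int i = 0; i < 3; ++i)
    if (c[i] != 'A' && c[i] != 'C' && c[i] != 'G' && c[i] != 'T') return true;
  return false;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &ch : r) {
    switch (ch) {
    case 'A': ch = 'T'; break;
    case 'C': ch = 'G'; break;
    case 'G': ch = 'C'; break;
    case 'T': ch = 'A'; break;
    default: ch = 'N';
    }
  }
  return r;
}

// Scan one strand: emit ORFs as [start, end) on the scanned string.
// An ORF runs from the first start codon after the previous stop (or an
// ambiguous codon, which a gene may not span) to the next in-frame stop,
// stop codon included.
static void scan_frames(const std::string &seq, int min_len,
                        std::vector<int> &starts, std::vector<int> &ends) {
  const int n = (int)seq.size();
  const char *p = seq.c_str();
  for (int frame = 0; frame < 3; ++frame) {
    int cur = -1;
    for (int i = frame; i + 3 <= n; i += 3) {
      const char *c = p + i;
      if (has_ambig(c)) { cur = -1; continue; }
      if (is_stop(c)) {
        if (cur >= 0 && (i + 3 - cur) >= min_len) {
          starts.push_back(cur);
          ends.push_back(i + 3);
        }
        cur = -1;
      } else if (cur < 0 && is_start(c)) {
        cur = i;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame orf_scan_cpp(std::string seq, int min_len) {
  std::vector<int> fs, fe, rs, re;
  scan_frames(seq, min_len, fs, fe);
  std::string rc = revcomp(seq);
  scan_frames(rc, min_len, rs, re);
  const int L = (int)seq.size();
  std::vector<int> start, end;
  std::vector<std::string> strand;
  for (size_t i = 0; i < fs.size(); ++i) {
    start.push_back(fs[i]); end.push_back(fe[i]); strand.push_back("+");
  }
  for (size_t i = 0; i < rs.size(); ++i) {
    // [s, e) on the reverse complement maps to [L - e, L - s) forward
    start.push_back(L - re[i]); end.push_back(L - rs[i]); strand.push_back("-");
  }
  // order by start, then end, then strand for determinism
  std::vector<size_t> idx(start.size());
  for (size_t i = 0; i < idx.size(); ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
    if (start[a] != start[b]) return start[a] < start[b];
    if (end[a] != end[b]) return end[a] < end[b];
    return strand[a] < strand[b];
  });
  IntegerVector os(idx.size()), oe(idx.size());
  CharacterVector ostr(idx.size());
  for (size_t i = 0; i < idx.size(); ++i) {
    os[i] = start[idx[i]];
    oe[i] = end[idx[i]];
    ostr[i] = strand[idx[i]];
  }
  return DataFrame::create(_["start"] = os, _["end"] = oe,
                           _["strand"] = ostr,
                           _["stringsAsFactors"] = false);
}

// MinHash sketching --------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// Hashes are masked to 53 bits so they are exactly representable as R
// doubles; collisions at 2^53 are negligible for genome-scale k-mer sets.
static const uint64_t HASH_MASK = (1ULL << 53) - 1;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

// [[Rcpp::export]]
NumericVector minhash_sketch_cpp(std::string seq, int k, int s) {
  const int n = (int)seq.size();
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> seen;
  uint64_t fwd = 0, rev = 0;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int valid = 0; // length of current run of unambiguous bases
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
    if (++valid >= k) {
      uint64_t canon = std::min(fwd, rev);
      seen.insert(splitmix64(canon) & HASH_MASK);
    }
  }
  std::vector<uint64_t> h(seen.begin(), seen.end());
  std::sort(h.begin(), h.end());
  const int keep = std::min((int)h.size(), s);
  NumericVector out(keep);
  for (int i = 0; i < keep; ++i) out[i] = (double)h[i];
  return out;
}

// [[Rcpp::export]]
std::string fnv1a_hex_cpp(std::string x) {
  uint64_t h = 0xCBF29CE484222325ULL;
  for (unsigned char c : x) {
    h ^= (uint64_t)c;
    h *= 0x100000001B3ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
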