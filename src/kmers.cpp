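// Core k-mer machinery: 2-bit packed canonical counting, reference
// indexing and mismatch-tolerant lookup. k is limited to 1..32 so a
// k-mer fits one 64-bit word; numeric order of the packing equals
// lexicographic order over A<C<G<T, which canonicalization relies on.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstring>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

static const char BITS2BASE[4] = {'A', 'C', 'G', 'T'};

static std::string decode_kmer(uint64_t code, int k) {
  std::string s((size_t) k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[(size_t) i] = BITS2BASE[code & 3ULL];
    code >>= 2;
  }
  return s;
}

struct RollingKmer {
  // Streams a sequence; yields (canonical, fwd) codes once a full
  // window of unambiguous bases has been seen.
  int k;
  uint64_t mask, fwd, rev;
  int run;
  explicit RollingKmer(int k_) : k(k_), fwd(0), rev(0), run(0) {
    mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  }
  // returns true when a complete k-mer ends at this base
  bool push(char c) {
    int b = base2bits(c);
    if (b < 0) { run = 0; return false; }
    fwd = ((fwd << 2) | (uint64_t) b) & mask;
    rev = (rev >> 2) | ((uint64_t) (3 - b) << (2 * (k - 1)));
    if (++run >= k) return true;
    return false;
  }
  uint64_t canonical() const { return fwd < rev ? fwd : rev; }
};

// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, int min_count) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  // two-pass: collect raw codes, sort, then run-length count. For the
  // read volumes in scope this is markedly faster than hashing every
  // window, and yields lexicographically sorted output for free.
  std::vector<uint64_t> codes;
  long long total_windows = 0;
  {
    size_t approx = 0;
    for (R_xlen_t r = 0; r < reads.size(); ++r) {
      SEXP el = STRING_ELT(reads, r);
      if (el != NA_STRING) approx += (size_t) LENGTH(el);
    }
    codes.reserve(approx);
  }
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    SEXP el = STRING_ELT(reads, r);
    if (el == NA_STRING) continue;
    const char *s = CHAR(el);
    int n = (int) std::strlen(s);
    if (n >= k) total_windows += n - k + 1;
    RollingKmer roll(k);
    for (int i = 0; i < n; ++i) {
      if (roll.push(s[i])) codes.push_back(roll.canonical());
    }
  }
  std::sort(codes.begin(), codes.end());
  std::vector<std::pair<uint64_t, int> > keep;
  size_t i = 0, m = codes.size();
  while (i < m) {
    size_t j = i + 1;
    while (j < m && codes[j] == codes[i]) ++j;
    if ((int) (j - i) >= min_count)
      keep.push_back(std::make_pair(codes[i], (int) (j - i)));
    i = j;
  }
  CharacterVector kmers((R_xlen_t) keep.size());
  IntegerVector counts((R_xlen_t) keep.size());
  std::string buf;
  for (size_t t = 0; t < keep.size(); ++t) {
    buf = decode_kmer(keep[t].first, k);
    SET_STRING_ELT(kmers, (R_xlen_t) t, Rf_mkCharLen(buf.data(), k));
    counts[(R_xlen_t) t] = keep[t].second;
  }
  return List::create(_["kmers"] = kmers, _["counts"] = counts,
                      _["n_skipped"] = (double) (total_windows - (long long) m));
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector x) {
  R_xlen_t n = x.size();
  CharacterVector out(n);
  std::string rc;
  for (R_xlen_t i = 0; i < n; ++i) {
    SEXP el = STRING_ELT(x, i);
    if (el == NA_STRING) { out[i] = NA_STRING; continue; }
    const char *s = CHAR(el);
    size_t len = std::strlen(s);
    rc.assign(len, 'A');
    bool ok = true;
    std::string up(len, 'A');
    for (size_t j = 0; j < len; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { ok = false; break; }
      up[j] = BITS2BASE[b];
      rc[len - 1 - j] = BITS2BASE[3 - b];
    }
    if (!ok) { out[i] = NA_STRING; continue; }
    out[i] = (rc < up) ? rc : up;
  }
  return out;
}

// Sorted set difference of two canonical k-mer key vectors (k <= 32).
// [[Rcpp::export]]
List cpp_kmer_setdiff(CharacterVector a, CharacterVector b, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::vector<uint64_t> ca, cb;
  ca.reserve((size_t) a.size());
  cb.reserve((size_t) b.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    const char *s = CHAR(STRING_ELT(a, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t) base2bits(s[j]);
    ca.push_back(code);
  }
  for (R_xlen_t i = 0; i < b.size(); ++i) {
    const char *s = CHAR(STRING_ELT(b, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t) base2bits(s[j]);
    cb.push_back(code);
  }
  std::sort(ca.begin(), ca.end());
  std::sort(cb.begin(), cb.end());
  std::vector<uint64_t> only_a, only_b;
  size_t i = 0, j = 0;
  while (i < ca.size() && j < cb.size()) {
    if (ca[i] < cb[j]) only_a.push_back(ca[i++]);
    else if (cb[j] < ca[i]) only_b.push_back(cb[j++]);
    else { ++i; ++j; }
  }
  while (i < ca.size()) only_a.push_back(ca[i++]);
  while (j < cb.size()) only_b.push_back(cb[j++]);
  CharacterVector oa((R_xlen_t) only_a.size()), ob((R_xlen_t) only_b.size());
  for (size_t t = 0; t < only_a.size(); ++t) oa[(R_xlen_t) t] = decode_kmer(only_a[t], k);
  for (size_t t = 0; t < only_b.size(); ++t) ob[(R_xlen_t) t] = decode_kmer(only_b[t], k);
  return List::create(_["a_only"] = oa, _["b_only"] = ob);
}

// Index every k-mer of a reference under its canonical form. Keeps the
// first occurrence (scan order: sequence 1..n, left to right) and flags
// multi-locus k-mers.
// [[Rcpp::export]]
List cpp_index_reference(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  struct Loc { int lg; int pos; bool multi; };
  std::unordered_map<uint64_t, Loc> idx;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    const char *s = CHAR(STRING_ELT(seqs, r));
    int n = (int) std::strlen(s);
    RollingKmer roll(k);
    for (int i = 0; i < n; ++i) {
      if (!roll.push(s[i])) continue;
      uint64_t key = roll.canonical();
      std::unordered_map<uint64_t, Loc>::iterator it = idx.find(key);
      if (it == idx.end()) {
        Loc loc; loc.lg = (int) r + 1; loc.pos = i - k + 1; loc.multi = false;
        idx.insert(std::make_pair(key, loc));
      } else {
        it->second.multi = true;
      }
    }
  }
  std::vector<uint64_t> keys;
  keys.reserve(idx.size());
  for (std::unordered_map<uint64_t, Loc>::const_iterator it = idx.begin();
       it != idx.end(); ++it)
    keys.push_back(it->first);
  std::sort(keys.begin(), keys.end());
  R_xlen_t m = (R_xlen_t) keys.size();
  CharacterVector kmers(m);
  IntegerVector lg(m), start(m);
  LogicalVector multi(m);
  for (R_xlen_t t = 0; t < m; ++t) {
    const Loc &loc = idx[keys[(size_t) t]];
    kmers[t] = decode_kmer(keys[(size_t) t], k);
    lg[t] = loc.lg;
    start[t] = loc.pos;
    multi[t] = loc.multi;
  }
  return List::create(_["kmer"] = kmers, _["lg"] = lg, _["start"] = start,
                      _["multi"] = multi);
}

// Look queries up in an indexed reference; exact match first, then (if
// max_mismatch >= 1) all single-base substitution neighbours in a fixed
// deterministic order (position left to right, bases A<C<G<T).
// Returns, per query, the row of the index hit (1-based; NA = unmapped)
// and the number of mismatches of the hit.
// [[Rcpp::export]]
List cpp_lookup_kmers(CharacterVector queries, CharacterVector index_kmers,
                      int k, int max_mismatch) {
  if (k < 1 || k > 32) stop("k must be between 1 and 32");
  std::unordered_map<uint64_t, int> idx;
  idx.reserve((size_t) index_kmers.size() * 2);
  for (R_xlen_t i = 0; i < index_kmers.size(); ++i) {
    const char *s = CHAR(STRING_ELT(index_kmers, i));
    uint64_t code = 0;
    for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t) base2bits(s[j]);
    idx[code] = (int) i + 1;
  }
  uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  R_xlen_t n = queries.size();
  IntegerVector row(n), nmis(n);
  for (R_xlen_t q = 0; q < n; ++q) {
    const char *s = CHAR(STRING_ELT(queries, q));
    uint64_t fwd = 0;
    for (int j = 0; j < k; ++j) fwd = (fwd << 2) | (uint64_t) base2bits(s[j]);
    std::unordered_map<uint64_t, int>::const_iterator hit = idx.find(fwd);
    if (hit != idx.end()) { row[q] = hit->second; nmis[q] = 0; continue; }
    int found = NA_INTEGER, fm = NA_INTEGER;
    if (max_mismatch >= 1) {
      for (int pos = 0; pos < k && found == NA_INTEGER; ++pos) {
        int shift = 2 * (k - 1 - pos);
        uint64_t cur = (fwd >> shift) & 3ULL;
        for (uint64_t b = 0; b < 4; ++b) {
          if (b == cur) continue;
          uint64_t var = (fwd & ~(3ULL << shift)) | (b << shift);
          // neighbour must itself be canonicalized before lookup
          uint64_t rc = 0, tmp = var;
          for (int j = 0; j < k; ++j) { rc = (rc << 2) | (3ULL - (tmp & 3ULL)); tmp >>= 2; }
          rc &= mask;
          uint64_t key = var < rc ? var : rc;
          std::unordered_map<uint64_t, int>::const_iterator h2 = idx.find(key);
          if (h2 != idx.end()) { found = h2->second; fm = 1; break; }
        }
      }
    }
    row[q] = found;
    nmis[q] = fm;
  }
  return List::create(_["row"] = row, _["mismatches"] = nmis);
}
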