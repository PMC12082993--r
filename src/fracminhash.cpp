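// Core hashing engine: MurmurHash3 x64_128 (first 64 bits, as used by
// sourmash/frac-kmc), canonical k-mer streaming, and FracMinHash
// thresholding. All 64-bit arithmetic stays in C++; hash values cross into
// R as decimal strings because R has no native unsigned 64-bit type.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <cmath>
#include <string>
#include <vector>
#include <algorithm>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// MurmurHash3 x64_128, from Austin Appleby's public-domain reference.

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

static inline uint64_t getblock64(const uint8_t* p, size_t i) {
  uint64_t k;
  std::memcpy(&k, p + i * 8, 8);  // little-endian hosts only (x86/arm64)
  return k;
}

// first 64 bits (h1) of the 128-bit digest
static uint64_t murmur3_x64_128_h1(const void* key, size_t len, uint32_t seed) {
  const uint8_t* data = (const uint8_t*)key;
  const size_t nblocks = len / 16;

  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;

  for (size_t i = 0; i < nblocks; i++) {
    uint64_t k1 = getblock64(data, i * 2 + 0);
    uint64_t k2 = getblock64(data, i * 2 + 1);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t* tail = data + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= ((uint64_t)tail[14]) << 48; // fall through
  case 14: k2 ^= ((uint64_t)tail[13]) << 40;
  case 13: k2 ^= ((uint64_t)tail[12]) << 32;
  case 12: k2 ^= ((uint64_t)tail[11]) << 24;
  case 11: k2 ^= ((uint64_t)tail[10]) << 16;
  case 10: k2 ^= ((uint64_t)tail[9])  << 8;
  case  9: k2 ^= ((uint64_t)tail[8])  << 0;
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
  case  8: k1 ^= ((uint64_t)tail[7]) << 56;
  case  7: k1 ^= ((uint64_t)tail[6]) << 48;
  case  6: k1 ^= ((uint64_t)tail[5]) << 40;
  case  5: k1 ^= ((uint64_t)tail[4]) << 32;
  case  4: k1 ^= ((uint64_t)tail[3]) << 24;
  case  3: k1 ^= ((uint64_t)tail[2]) << 16;
  case  2: k1 ^= ((uint64_t)tail[1]) << 8;
  case  1: k1 ^= ((uint64_t)tail[0]) << 0;
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= len; h2 ^= len;
  h1 += h2; h2 += h1;
  h1 = fmix64(h1); h2 = fmix64(h2);
  h1 += h2; // h2 += h1 not needed for h1
  return h1;
}

// ---------------------------------------------------------------------------
// FracMinHash acceptance rule: keep h iff h <= floor(s * 2^64), with the
// conventions s = 0 -> empty, s = 1 -> keep everything. The product is
// evaluated in 80-bit long double so floor() is exact for any double s.

static const long double TWO64 = 18446744073709551616.0L;

static inline uint64_t threshold_u64(double s) {
  long double t = floorl((long double)s * TWO64);
  if (t <= 0.0L) return 0;
  if (t >= TWO64) return UINT64_MAX;
  return (uint64_t)t;
}

static inline bool hash_accepted(uint64_t h, double s, uint64_t thr) {
  if (s <= 0.0) return false;
  if (s >= 1.0) return true;
  return h <= thr;
}

// [[Rcpp::export]]
std::string cpp_threshold_str(double scale) {
  if (scale <= 0.0) return "0";
  if (scale >= 1.0) return "18446744073709551616"; // 2^64 itself
  char buf[32];
  snprintf(buf, sizeof(buf), "%llu", (unsigned long long)threshold_u64(scale));
  return std::string(buf);
}

// ---------------------------------------------------------------------------
// DNA utilities

static inline char norm_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'A';
  case 'C': case 'c': return 'C';
  case 'G': case 'g': return 'G';
  case 'T': case 't': return 'T';
  default: return 0;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  default:  return 'A'; // 'T'
  }
}

// canonical = lexicographic min of the (normalized) k-mer and its reverse
// complement; returns false if any base is not ACGT
static bool canonical_kmer(const char* kmer, size_t k, std::string& out) {
  out.resize(k);
  for (size_t i = 0; i < k; i++) {
    char b = norm_base(kmer[i]);
    if (!b) return false;
    out[i] = b;
  }
  // compare forward with reverse complement without materializing it
  bool use_rc = false;
  for (size_t i = 0; i < k; i++) {
    char rc = comp_base(out[k - 1 - i]);
    if (rc < out[i]) { use_rc = true; break; }
    if (rc > out[i]) break;
  }
  if (use_rc) {
    std::string rc(k, 'A');
    for (size_t i = 0; i < k; i++) rc[i] = comp_base(out[k - 1 - i]);
    out.swap(rc);
  }
  return true;
}

static std::string u64_to_str(uint64_t v) {
  char buf[24];
  snprintf(buf, sizeof(buf), "%llu", (unsigned long long)v);
  return std::string(buf);
}

static bool str_to_u64(const char* s, uint64_t& out) {
  if (!s || !*s) return false;
  uint64_t v = 0;
  for (const char* p = s; *p; ++p) {
    if (*p < '0' || *p > '9') return false;
    uint64_t d = (uint64_t)(*p - '0');
    if (v > (UINT64_MAX - d) / 10) return false; // overflow
    v = v * 10 + d;
  }
  out = v;
  return true;
}

static CharacterVector u64vec_to_strvec(std::vector<uint64_t>& v) {
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  CharacterVector out(v.size());
  for (size_t i = 0; i < v.size(); i++) out[i] = u64_to_str(v[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Exported k-mer operations

// [[Rcpp::export]]
CharacterVector cpp_canonicalize(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  std::string can;
  for (R_xlen_t i = 0; i < kmers.size(); i++) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if (!canonical_kmer(s, std::strlen(s), can))
      stop("invalid k-mer '%s': contains a non-ACGT character", s);
    out[i] = can;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_stream_kmers(std::string seq, int k) {
  std::vector<std::string> res;
  if ((int)seq.size() >= k) {
    std::string can;
    for (size_t i = 0; i + k <= seq.size(); i++) {
      if (canonical_kmer(seq.c_str() + i, (size_t)k, can))
        res.push_back(can);
    }
  }
  return wrap(res);
}

// hash arbitrary byte strings (already-canonical k-mers) -> decimal strings
// [[Rcpp::export]]
CharacterVector cpp_hash_strings(CharacterVector keys, int seed) {
  CharacterVector out(keys.size());
  for (R_xlen_t i = 0; i < keys.size(); i++) {
    const char* s = CHAR(STRING_ELT(keys, i));
    out[i] = u64_to_str(murmur3_x64_128_h1(s, std::strlen(s), (uint32_t)seed));
  }
  return out;
}

// Sketch a set of k-mer strings: canonicalize (optionally), hash, keep
// values under the threshold; optionally count distinct canonical k-mers.
// [[Rcpp::export]]
List cpp_sketch_kmers(CharacterVector kmers, int seed, double scale,
                      bool canonicalize, bool track_cardinality) {
  uint64_t thr = threshold_u64(scale);
  std::vector<uint64_t> kept;
  std::unordered_set<std::string> distinct;
  std::unordered_set<uint64_t> seen_hash;
  std::string can;
  for (R_xlen_t i = 0; i < kmers.size(); i++) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    const char* key = s;
    if (canonicalize) {
      if (!canonical_kmer(s, std::strlen(s), can))
        stop("invalid k-mer '%s': contains a non-ACGT character", s);
      key = can.c_str();
    }
    if (track_cardinality) distinct.insert(key);
    uint64_t h = murmur3_x64_128_h1(key, std::strlen(key), (uint32_t)seed);
    if (hash_accepted(h, scale, thr)) kept.push_back(h);
  }
  double card = track_cardinality ? (double)distinct.size() : NA_REAL;
  return List::create(_["hashes"] = u64vec_to_strvec(kept),
                      _["n_distinct"] = card);
}

// Sketch whole sequences: every valid length-k window, canonicalized.
// [[Rcpp::export]]
List cpp_sketch_sequences(CharacterVector seqs, int k, int seed, double scale,
                          bool track_cardinality) {
  uint64_t thr = threshold_u64(scale);
  std::vector<uint64_t> kept;
  std::unordered_set<std::string> distinct;
  std::string can;
  for (R_xlen_t j = 0; j < seqs.size(); j++) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    size_t n = std::strlen(s);
    if ((int)n < k) continue;
    for (size_t i = 0; i + (size_t)k <= n; i++) {
      if (!canonical_kmer(s + i, (size_t)k, can)) continue;
      if (track_cardinality) distinct.insert(can);
      uint64_t h = murmur3_x64_128_h1(can.c_str(), (size_t)k, (uint32_t)seed);
      if (hash_accepted(h, scale, thr)) kept.push_back(h);
    }
  }
  double card = track_cardinality ? (double)distinct.size() : NA_REAL;
  return List::create(_["hashes"] = u64vec_to_strvec(kept),
                      _["n_distinct"] = card);
}

// ---------------------------------------------------------------------------
// Integer-universe elements (simulation): element i is hashed as its
// 8-byte little-endian encoding, the same byte-level contract as k-mers.

// [[Rcpp::export]]
LogicalVector cpp_ints_in_sketch(NumericVector elements, int seed, double scale) {
  uint64_t thr = threshold_u64(scale);
  LogicalVector out(elements.size());
  uint8_t buf[8];
  for (R_xlen_t i = 0; i < elements.size(); i++) {
    uint64_t e = (uint64_t)elements[i];
    std::memcpy(buf, &e, 8); // little-endian host
    uint64_t h = murmur3_x64_128_h1(buf, 8, (uint32_t)seed);
    out[i] = hash_accepted(h, scale, thr);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_ints_sketch_hashes(NumericVector elements, int seed,
                                       double scale) {
  uint64_t thr = threshold_u64(scale);
  std::vector<uint64_t> kept;
  uint8_t buf[8];
  for (R_xlen_t i = 0; i < elements.size(); i++) {
    uint64_t e = (uint64_t)elements[i];
    std::memcpy(buf, &e, 8);
    uint64_t h = murmur3_x64_128_h1(buf, 8, (uint32_t)seed);
    if (hash_accepted(h, scale, thr)) kept.push_back(h);
  }
  return u64vec_to_strvec(kept);
}

// ---------------------------------------------------------------------------
// uint64-as-decimal-string helpers for the signature reader and set algebra

// [[Rcpp::export]]
List cpp_u64str_validate_sort(CharacterVector hashes) {
  std::vector<uint64_t> v(hashes.size());
  for (R_xlen_t i = 0; i < hashes.size(); i++) {
    if (STRING_ELT(hashes, i) == NA_STRING ||
        !str_to_u64(CHAR(STRING_ELT(hashes, i)), v[i]))
      stop("hashes[%d] is not a valid unsigned 64-bit decimal value", (int)(i + 1));
  }
  bool was_sorted = std::is_sorted(v.begin(), v.end()) &&
    std::adjacent_find(v.begin(), v.end()) == v.end();
  return List::create(_["hashes"] = u64vec_to_strvec(v),
                      _["was_sorted_unique"] = was_sorted);
}

// [[Rcpp::export]]
LogicalVector cpp_u64str_below_threshold(CharacterVector hashes, double scale) {
  uint64_t thr = threshold_u64(scale);
  LogicalVector out(hashes.size());
  for (R_xlen_t i = 0; i < hashes.size(); i++) {
    uint64_t v;
    if (!str_to_u64(CHAR(STRING_ELT(hashes, i)), v))
      stop("hashes[%d] is not a valid unsigned 64-bit decimal value", (int)(i + 1));
    out[i] = hash_accepted(v, scale, thr);
  }
  return out;
}

// intersection count of two sorted-unique uint64 decimal-string vectors
// [[Rcpp::export]]
double cpp_u64str_intersection_size(CharacterVector a, CharacterVector b) {
  R_xlen_t i = 0, j = 0;
  double n = 0;
  uint64_t va, vb;
  while (i < a.size() && j < b.size()) {
    str_to_u64(CHAR(STRING_ELT(a, i)), va);
    str_to_u64(CHAR(STRING_ELT(b, j)), vb);
    if (va == vb) { n++; i++; j++; }
    else if (va < vb) i++;
    else j++;
  }
  return n;
}
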