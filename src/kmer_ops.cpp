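#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// 2-bit base encoding A=0, C=1, G=2, T=3 so that numeric order on packed
// k-mers equals lexicographic order on the strings.
static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline void check_acgt(const std::string& s) {
  for (size_t i = 0; i < s.size(); ++i) {
    if (base_code(s[i]) < 0)
      stop("non-ACGT character '%c' in sequence", s[i]);
  }
}

// 64-bit avalanche finalizer (MurmurHash3 fmix64, public domain).
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 33;
  x *= 0xff51afd7ed558ccdULL;
  x ^= x >> 33;
  x *= 0xc4ceb9fe1a85ec53ULL;
  x ^= x >> 33;
  return x;
}

// Seeded hash of a 2-bit packed canonical k-mer. The seed is mixed first so
// that nearby seeds give unrelated hash functions.
static inline uint64_t kmer_hash(uint64_t packed, uint64_t seed) {
  return mix64(packed ^ mix64(seed + 0x9e3779b97f4a7c15ULL));
}

static inline uint64_t pack2bit(const char* s, int k) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int b = base_code(s[i]);
    if (b < 0) stop("non-ACGT character '%c' in sequence", s[i]);
    v = (v << 2) | (uint64_t)b;
  }
  return v;
}

static inline std::string unpack2bit(uint64_t v, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = BASES[v & 3ULL];
    v >>= 2;
  }
  return s;
}

static inline std::string revcomp_str(const std::string& s) {
  std::string r(s.size(), 'A');
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base_code(s[s.size() - 1 - i]);
    if (b < 0) stop("non-ACGT character '%c' in sequence", s[s.size() - 1 - i]);
    r[i] = BASES[3 - b];
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp_str(s);
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    check_acgt(s);
    std::string r = revcomp_str(s);
    out[i] = (s <= r) ? s : r;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_encode2bit(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.size() > 26) stop("2-bit numeric codes support length <= 26");
    out[i] = (double)pack2bit(s.c_str(), (int)s.size());
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode2bit(NumericVector codes, int len) {
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    out[i] = unpack2bit((uint64_t)codes[i], len);
  }
  return out;
}

// Per-position minimizer values over a fragment: for every m-mer position,
// min(code(m-mer), code(revcomp(m-mer))), so the minimizer of a window is the
// smallest value over its positions and is strand-symmetric by construction.
static void mmer_values(const std::string& s, int m, std::vector<uint64_t>& val) {
  size_t n = s.size();
  val.assign(n - m + 1, 0);
  uint64_t mask = (m == 32) ? ~0ULL : ((1ULL << (2 * m)) - 1);
  uint64_t f = 0, rc = 0;
  int shift = 2 * (m - 1);
  for (size_t i = 0; i < n; ++i) {
    int b = base_code(s[i]);
    f = ((f << 2) | (uint64_t)b) & mask;
    rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
    if ((int)i >= m - 1) val[i - m + 1] = std::min(f, rc);
  }
}

// [[Rcpp::export]]
CharacterVector cpp_minimizers(CharacterVector kmers, int m) {
  R_xlen_t n = kmers.size();
  CharacterVector out(n);
  std::vector<uint64_t> val;
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() <= m) stop("minimizer length m must be < k");
    check_acgt(s);
    mmer_values(s, m, val);
    uint64_t best = *std::min_element(val.begin(), val.end());
    out[i] = unpack2bit(best, m);
  }
  return out;
}

// Decompose reads into super-k-mers. Reads are split at non-ACGT characters;
// each fragment of length >= k is cut into maximal runs of consecutive
// k-mers sharing the same (both-strand) minimizer.
// [[Rcpp::export]]
DataFrame cpp_super_kmers(CharacterVector reads, int k, int m) {
  if (m >= k) stop("minimizer length m must be < k");
  std::vector<int> out_read;
  std::vector<std::string> out_seq;
  std::vector<std::string> out_mini;
  std::vector<uint64_t> val;
  std::vector<uint64_t> winmin;

  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string read = as<std::string>(reads[r]);
    size_t i = 0, n = read.size();
    while (i < n) {
      while (i < n && base_code(read[i]) < 0) ++i;
      size_t j = i;
      while (j < n && base_code(read[j]) >= 0) ++j;
      if (j - i >= (size_t)k) {
        std::string frag = read.substr(i, j - i);
        size_t L = frag.size();
        mmer_values(frag, m, val);
        size_t nk = L - k + 1;
        winmin.assign(nk, 0);
        int w = k - m + 1;  // m-mer positions per k-mer window
        for (size_t t = 0; t < nk; ++t) {
          uint64_t b = val[t];
          for (int u = 1; u < w; ++u) b = std::min(b, val[t + u]);
          winmin[t] = b;
        }
        size_t start = 0;
        for (size_t t = 1; t <= nk; ++t) {
          if (t == nk || winmin[t] != winmin[start]) {
            out_read.push_back((int)(r + 1));
            out_seq.push_back(frag.substr(start, (t - start) + k - 1));
            out_mini.push_back(unpack2bit(winmin[start], m));
            start = t;
          }
        }
      }
      i = j;
    }
  }
  return DataFrame::create(
      _["read"] = out_read,
      _["sequence"] = out_seq,
      _["minimizer"] = out_mini,
      _["stringsAsFactors"] = false);
}

// Slide a k-window over each sequence, canonicalize, tally. Sequences shorter
// than k contribute nothing. Output sorted by packed 2-bit code, which equals
// lexicographic order on the k-mer strings.
static void tally_canonical(CharacterVector seqs, int k,
                            std::unordered_map<uint64_t, uint32_t>& tab) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  int shift = 2 * (k - 1);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < k) continue;
    uint64_t f = 0, rc = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      int b = base_code(s[j]);
      if (b < 0) stop("non-ACGT character '%c' in counted sequence", s[j]);
      f = ((f << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
      if ((int)j >= k - 1) {
        uint64_t can = std::min(f, rc);
        ++tab[can];
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_count_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tally_canonical(seqs, k, tab);
  std::vector<uint64_t> keys;
  keys.reserve(tab.size());
  for (auto& kv : tab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  CharacterVector kk(keys.size());
  IntegerVector cc(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kk[i] = unpack2bit(keys[i], k);
    cc[i] = (int)tab[keys[i]];
  }
  return DataFrame::create(_["key"] = kk, _["count"] = cc,
                           _["stringsAsFactors"] = false);
}

// Hash counting: canonical k-mers are replaced by their hash index
// p*s + (H(kmer, seed) mod s) before tallying; distinct k-mers may collide.
// [[Rcpp::export]]
DataFrame cpp_count_hashes(CharacterVector seqs, int k, int p, double s,
                           double seed) {
  if (k < 1 || k > 32) stop("k must be in [1, 32]");
  std::unordered_map<uint64_t, uint32_t> tab;
  tally_canonical(seqs, k, tab);
  uint64_t su = (uint64_t)s;
  uint64_t base = (uint64_t)p * su;
  uint64_t sd = (uint64_t)seed;
  std::unordered_map<uint64_t, uint32_t> htab;
  for (auto& kv : tab) {
    uint64_t idx = base + (kmer_hash(kv.first, sd) % su);
    htab[idx] += kv.second;
  }
  std::vector<uint64_t> keys;
  keys.reserve(htab.size());
  for (auto& kv : htab) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  NumericVector kk(keys.size());
  IntegerVector cc(keys.size());
  for (size_t i = 0; i < keys.size(); ++i) {
    kk[i] = (double)keys[i];
    cc[i] = (int)htab[keys[i]];
  }
  return DataFrame::create(_["key"] = kk, _["count"] = cc);
}

// Hash indices for explicit k-mers (canonicalized internally).
// [[Rcpp::export]]
NumericVector cpp_hash_indices(CharacterVector kmers, int p, double s,
                               double seed) {
  uint64_t su = (uint64_t)s;
  uint64_t base = (uint64_t)p * su;
  uint64_t sd = (uint64_t)seed;
  NumericVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string str = as<std::string>(kmers[i]);
    if (str.size() > 32) stop("k must be <= 32");
    check_acgt(str);
    std::string r = revcomp_str(str);
    const std::string& can = (str <= r) ? str : r;
    uint64_t packed = pack2bit(can.c_str(), (int)can.size());
    out[i] = (double)(base + (kmer_hash(packed, sd) % su));
  }
  return out;
}

// ---- bit vector / bit matrix kernels (LSB-first within each byte) ----

static inline bool get_bit(const Rbyte* p, uint64_t idx) {
  return (p[idx >> 3] >> (idx & 7)) & 1;
}
static inline void set_bit(Rbyte* p, uint64_t idx) {
  p[idx >> 3] |= (Rbyte)(1u << (idx & 7));
}

// [[Rcpp::export]]
RawVector cpp_set_bits(RawVector payload, NumericVector idx) {
  RawVector out = clone(payload);
  uint64_t nbits = (uint64_t)out.size() * 8ULL;
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    uint64_t b = (uint64_t)idx[i];
    if (b >= nbits) stop("bit index out of range");
    set_bit(out.begin(), b);
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_get_bits(RawVector payload, NumericVector idx) {
  LogicalVector out(idx.size());
  uint64_t nbits = (uint64_t)payload.size() * 8ULL;
  for (R_xlen_t i = 0; i < idx.size(); ++i) {
    uint64_t b = (uint64_t)idx[i];
    if (b >= nbits) stop("bit index out of range");
    out[i] = get_bit(payload.begin(), b);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_popcount(RawVector payload) {
  double n = 0;
  for (R_xlen_t i = 0; i < payload.size(); ++i) {
    Rbyte b = payload[i];
    while (b) { n += b & 1; b >>= 1; }
  }
  return n;
}

// Row-major packed bit matrix transposition: input has `rows` rows of
// ceil(cols/8) bytes, output has `cols` rows of ceil(rows/8) bytes.
// [[Rcpp::export]]
RawVector cpp_transpose_bits(RawVector payload, double rows, double cols) {
  uint64_t R = (uint64_t)rows, C = (uint64_t)cols;
  uint64_t istride = (C + 7) / 8, ostride = (R + 7) / 8;
  if ((uint64_t)payload.size() != R * istride)
    stop("payload size does not match rows x ceil(cols/8)");
  RawVector out(R == 0 || C == 0 ? 0 : C * ostride);
  const Rbyte* in = payload.begin();
  Rbyte* o = out.begin();
  for (uint64_t i = 0; i < R; ++i) {
    const Rbyte* rowp = in + i * istride;
    for (uint64_t jb = 0; jb < istride; ++jb) {
      Rbyte byte = rowp[jb];
      if (!byte) continue;
      for (int b = 0; b < 8; ++b) {
        if ((byte >> b) & 1) {
          uint64_t j = jb * 8 + b;
          if (j < C) o[j * ostride + (i >> 3)] |= (Rbyte)(1u << (i & 7));
        }
      }
    }
  }
  return out;
}

// Dense hash-major sub-matrix builder: `offsets` are 0-based row indices
// (hash index minus p*s) and `bits` the per-key presence pattern across the
// C samples. Rows never touched stay all-zero.
// [[Rcpp::export]]
RawVector cpp_build_submatrix(NumericVector offsets, LogicalMatrix bits,
                              double s) {
  uint64_t S = (uint64_t)s;
  int C = bits.ncol();
  uint64_t stride = ((uint64_t)C + 7) / 8;
  RawVector out(S * stride);
  Rbyte* o = out.begin();
  if (offsets.size() != bits.nrow())
    stop("offsets and bits row count differ");
  for (R_xlen_t t = 0; t < offsets.size(); ++t) {
    uint64_t r = (uint64_t)offsets[t];
    if (r >= S) stop("hash offset out of partition range");
    for (int c = 0; c < C; ++c) {
      if (bits(t, c)) o[r * stride + (c >> 3)] |= (Rbyte)(1u << (c & 7));
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalMatrix cpp_unpack_rows(RawVector payload, double rows, double cols) {
  uint64_t R = (uint64_t)rows, C = (uint64_t)cols;
  uint64_t stride = (C + 7) / 8;
  LogicalMatrix out((int)R, (int)C);
  const Rbyte* p = payload.begin();
  for (uint64_t i = 0; i < R; ++i)
    for (uint64_t j = 0; j < C; ++j)
      out((int)i, (int)j) = get_bit(p + i * stride, j);
  return out;
}

// [[Rcpp::export]]
RawVector cpp_pack_rows(LogicalMatrix bits) {
  uint64_t R = bits.nrow(), C = bits.ncol();
  uint64_t stride = (C + 7) / 8;
  RawVector out(R * stride);
  Rbyte* p = out.begin();
  for (uint64_t i = 0; i < R; ++i)
    for (uint64_t j = 0; j < C; ++j)
      if (bits((int)i, (int)j)) p[i * stride + (j >> 3)] |= (Rbyte)(1u << (j & 7));
  return out;
}

// FNV-1a digest of an integer vector, folded to < 2^53 so it survives an R
// double round-trip; used to fingerprint partition maps in file headers.
// [[Rcpp::export]]
double cpp_digest_ints(IntegerVector x) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    uint32_t v = (uint32_t)x[i];
    for (int b = 0; b < 4; ++b) {
      h ^= (v >> (8 * b)) & 0xff;
      h *= 0x100000001b3ULL;
    }
  }
  return (double)(h & ((1ULL << 53) - 1));
}

// Random k-mers from R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_random_kmers(int n, int k) {
  CharacterVector out(n);
  GetRNGstate();
  for (int i = 0; i < n; ++i) {
    std::string s(k, 'A');
    for (int j = 0; j < k; ++j) {
      int b = (int)(unif_rand() * 4.0);
      if (b > 3) b = 3;
      s[j] = BASES[b];
    }
    out[i] = s;
  }
  PutRNGstate();
  return out;
}

// All k-mers of the ACGT fragments of each sequence, in read order
// (not canonicalized); fragments shorter than k yield nothing.
// [[Rcpp::export]]
CharacterVector cpp_extract_kmers(CharacterVector seqs, int k) {
  std::vector<std::string> out;
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    size_t i = 0, n = s.size();
    while (i < n) {
      while (i < n && base_code(s[i]) < 0) ++i;
      size_t j = i;
      while (j < n && base_code(s[j]) >= 0) ++j;
      if (j - i >= (size_t)k) {
        for (size_t t = i; t + k <= j; ++t) out.push_back(s.substr(t, k));
      }
      i = j;
    }
  }
  return wrap(out);
}
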