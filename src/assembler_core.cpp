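// Core engine: 2-bit packed k-mer codec, partitioned sorted-vector k-mer store
// with prefix acceleration tables, read-adjacency linkage construction, graph
// simplification (low-frequency dead ends, tips), linear-chain compaction, and
// k-mer based read-to-node mapping used by the contig and scaffold stages.
//
// Conventions:
//  - bases A,C,G,T = 0,1,2,3; the FIRST base of a k-mer is the most
//    significant base pair of the packed 64-bit code, so integer order on
//    codes equals lexicographic order on the strings.
//  - k is odd and <= 31, so no k-mer is its own reverse complement and the
//    canonical (lexicographically smaller) strand is always unambiguous.
//  - adjacency mask: low nibble = right-extensions of the canonical strand
//    (bit index = base code of the following base); high nibble =
//    left-extensions (bit index = base code of the COMPLEMENT of the
//    preceding base, i.e. the right-extension of the reverse strand).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>
#include <map>
#include <algorithm>
#include <unordered_map>
#include <unordered_set>
#include <fstream>

using namespace Rcpp;

static const uint64_t LCG_A = 6364136223846793005ULL;
static const uint64_t LCG_C = 1442695040888963407ULL;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 0; // non-ACGT sanitized to A upstream; defensive here
  }
}

static inline char code_base(int b) { return "ACGT"[b & 3]; }

static inline uint64_t kmask(int k) { return (1ULL << (2 * k)) - 1ULL; }

static inline uint64_t rc_code(uint64_t x, int k) {
  uint64_t y = 0;
  for (int i = 0; i < k; ++i) {
    y = (y << 2) | (3ULL - (x & 3ULL));
    x >>= 2;
  }
  return y;
}

static inline uint64_t lcg_hash(uint64_t x) {
  return (LCG_A * x + LCG_C) >> 33;
}

static inline int part_of(uint64_t canon, int nparts) {
  return (int)(lcg_hash(canon) % (uint64_t)nparts);
}

static inline uint64_t raw_to_code(const Rbyte* p) {
  uint64_t x = 0;
  for (int i = 7; i >= 0; --i) x = (x << 8) | (uint64_t)p[i];
  return x;
}

static inline void code_to_raw(uint64_t x, Rbyte* p) {
  for (int i = 0; i < 8; ++i) { p[i] = (Rbyte)(x & 0xFF); x >>= 8; }
}

static std::string decode_str(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = code_base((int)(x & 3)); x >>= 2; }
  return s;
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = code_base(3 - base_code(c));
  return r;
}

// ---------------------------------------------------------------- codec API

// [[Rcpp::export]]
RawMatrix cpp_encode(CharacterVector seqs, int k) {
  R_xlen_t n = seqs.size();
  RawMatrix out(8, n);
  for (R_xlen_t j = 0; j < n; ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    if ((int)std::strlen(s) != k)
      stop("sequence %d has length %d, expected k = %d", (int)j + 1,
           (int)std::strlen(s), k);
    uint64_t x = 0;
    for (int i = 0; i < k; ++i) {
      char c = s[i];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' &&
          c != 'a' && c != 'c' && c != 'g' && c != 't')
        stop("invalid base '%c' in sequence %d (sanitize first)", c, (int)j + 1);
      x = (x << 2) | (uint64_t)base_code(c);
    }
    code_to_raw(x, &out(0, j));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(RawMatrix codes, int k) {
  R_xlen_t n = codes.ncol();
  CharacterVector out(n);
  for (R_xlen_t j = 0; j < n; ++j)
    out[j] = decode_str(raw_to_code(&codes(0, j)), k);
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_revcomp(RawMatrix codes, int k) {
  R_xlen_t n = codes.ncol();
  RawMatrix out(8, n);
  for (R_xlen_t j = 0; j < n; ++j)
    code_to_raw(rc_code(raw_to_code(&codes(0, j)), k), &out(0, j));
  return out;
}

// [[Rcpp::export]]
RawMatrix cpp_canonical(RawMatrix codes, int k) {
  R_xlen_t n = codes.ncol();
  RawMatrix out(8, n);
  for (R_xlen_t j = 0; j < n; ++j) {
    uint64_t x = raw_to_code(&codes(0, j));
    uint64_t r = rc_code(x, k);
    code_to_raw(std::min(x, r), &out(0, j));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_partition_of(RawMatrix codes, int k, int n_parts) {
  R_xlen_t n = codes.ncol();
  IntegerVector out(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    uint64_t x = raw_to_code(&codes(0, j));
    uint64_t c = std::min(x, rc_code(x, k));
    out[j] = part_of(c, n_parts);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_code_to_number(RawMatrix codes) {
  R_xlen_t n = codes.ncol();
  NumericVector out(n);
  for (R_xlen_t j = 0; j < n; ++j)
    out[j] = (double)raw_to_code(&codes(0, j));
  return out;
}

// Enumerate the k-mers of one read: 0-based positions, canonical codes and a
// flag saying whether the observed strand already was the canonical one.
// [[Rcpp::export]]
List cpp_enumerate(std::string read, int k) {
  int len = (int)read.size();
  int n = std::max(0, len - k + 1);
  IntegerVector pos(n);
  RawMatrix codes(8, n);
  LogicalVector fwd(n);
  uint64_t mask = kmask(k), f = 0, r = 0;
  int shift = 2 * (k - 1);
  for (int i = 0; i < len; ++i) {
    int b = base_code(read[i]);
    f = ((f << 2) | (uint64_t)b) & mask;
    r = (r >> 2) | ((uint64_t)(3 - b) << shift);
    if (i >= k - 1) {
      int j = i - k + 1;
      pos[j] = j;
      fwd[j] = (f <= r);
      code_to_raw(std::min(f, r), &codes(0, j));
    }
  }
  return List::create(_["pos"] = pos, _["code"] = codes, _["is_canonical"] = fwd);
}

// ---------------------------------------------------------------- the store

struct Part {
  std::vector<uint64_t> code;
  std::vector<uint16_t> mult;
  std::vector<uint8_t> adj;
  std::vector<uint8_t> dead;
  std::vector<uint32_t> accel; // size 2^reff + 1; accel[p]..accel[p+1] = range
};

struct Store {
  int k, nparts, rbits, reff;
  std::vector<Part> parts;
};

static void build_accel(Part& P, int twok, int reff) {
  size_t nb = ((size_t)1 << reff) + 1;
  P.accel.assign(nb, 0);
  int shift = twok - reff;
  for (uint64_t c : P.code) P.accel[(c >> shift) + 1]++;
  for (size_t i = 1; i < nb; ++i) P.accel[i] += P.accel[i - 1];
}

// index of canonical code in its partition, or -1 when absent/tombstoned
static inline long find_idx(const Store& S, uint64_t canon, int& part_out) {
  int p = part_of(canon, S.nparts);
  part_out = p;
  const Part& P = S.parts[p];
  int shift = 2 * S.k - S.reff;
  uint64_t pre = canon >> shift;
  size_t lo = (size_t)P.accel[pre], hi = (size_t)P.accel[pre + 1];
  const uint64_t* base = P.code.data();
  const uint64_t* it = std::lower_bound(base + lo, base + hi, canon);
  if (it != base + hi && *it == canon) {
    size_t idx = (size_t)(it - base);
    if (!P.dead[idx]) return (long)idx;
  }
  return -1;
}

static inline int pc4(int x) {
  return (x & 1) + ((x >> 1) & 1) + ((x >> 2) & 1) + ((x >> 3) & 1);
}

static Store* get_store(SEXP sp) {
  XPtr<Store> p(sp);
  return p.get();
}

// [[Rcpp::export]]
SEXP cpp_store_build(CharacterVector reads, int k, int nparts, int rbits) {
  XPtr<Store> ptr(new Store(), true);
  Store* S = ptr.get();
  S->k = k; S->nparts = nparts; S->rbits = rbits;
  S->reff = std::min(rbits, 2 * k);
  S->parts.resize(nparts);
  std::vector<std::vector<uint64_t>> bufs(nparts);
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  for (R_xlen_t rr = 0; rr < reads.size(); ++rr) {
    const char* s = CHAR(STRING_ELT(reads, rr));
    int len = (int)std::strlen(s);
    uint64_t f = 0, r = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (i >= k - 1) {
        uint64_t c = std::min(f, r);
        bufs[part_of(c, nparts)].push_back(c);
      }
    }
  }
  for (int p = 0; p < nparts; ++p) {
    std::vector<uint64_t>& v = bufs[p];
    std::sort(v.begin(), v.end());
    Part& P = S->parts[p];
    size_t i = 0, n = v.size();
    while (i < n) {
      size_t j = i;
      while (j < n && v[j] == v[i]) ++j;
      P.code.push_back(v[i]);
      P.mult.push_back((uint16_t)std::min<size_t>(j - i, 65535));
      ++i; i = j;
    }
    P.adj.assign(P.code.size(), 0);
    P.dead.assign(P.code.size(), 0);
    std::vector<uint64_t>().swap(v);
    build_accel(P, 2 * k, S->reff);
  }
  return ptr;
}

// [[Rcpp::export]]
SEXP cpp_store_from_records(int k, int nparts, int rbits, RawMatrix code,
                            IntegerVector mult, IntegerVector adj) {
  XPtr<Store> ptr(new Store(), true);
  Store* S = ptr.get();
  S->k = k; S->nparts = nparts; S->rbits = rbits;
  S->reff = std::min(rbits, 2 * k);
  S->parts.resize(nparts);
  std::vector<std::vector<std::pair<uint64_t, std::pair<int, int>>>> bufs(nparts);
  for (R_xlen_t j = 0; j < code.ncol(); ++j) {
    uint64_t c = raw_to_code(&code(0, j));
    bufs[part_of(c, nparts)].push_back({c, {mult[j], adj[j]}});
  }
  for (int p = 0; p < nparts; ++p) {
    auto& v = bufs[p];
    std::sort(v.begin(), v.end());
    Part& P = S->parts[p];
    size_t i = 0;
    while (i < v.size()) {
      uint64_t c = v[i].first;
      long m = 0; int a = 0;
      while (i < v.size() && v[i].first == c) {
        m += v[i].second.first; a |= v[i].second.second; ++i;
      }
      P.code.push_back(c);
      P.mult.push_back((uint16_t)std::min<long>(m, 65535));
      P.adj.push_back((uint8_t)a);
      P.dead.push_back(0);
    }
    build_accel(P, 2 * k, S->reff);
  }
  return ptr;
}

// [[Rcpp::export]]
List cpp_store_info(SEXP sp) {
  Store* S = get_store(sp);
  double alive = 0, total = 0;
  for (auto& P : S->parts) {
    total += (double)P.code.size();
    for (size_t i = 0; i < P.code.size(); ++i) if (!P.dead[i]) alive += 1;
  }
  return List::create(_["k"] = S->k, _["n_parts"] = S->nparts,
                      _["r"] = S->rbits, _["r_effective"] = S->reff,
                      _["n_alive"] = alive, _["n_slots"] = total);
}

// [[Rcpp::export]]
List cpp_store_records(SEXP sp) {
  Store* S = get_store(sp);
  size_t n = 0;
  for (auto& P : S->parts)
    for (size_t i = 0; i < P.code.size(); ++i) if (!P.dead[i]) ++n;
  RawMatrix code(8, (int)n);
  IntegerVector mult((int)n), adj((int)n), part((int)n);
  size_t j = 0;
  for (int p = 0; p < S->nparts; ++p) {
    Part& P = S->parts[p];
    for (size_t i = 0; i < P.code.size(); ++i) {
      if (P.dead[i]) continue;
      code_to_raw(P.code[i], &code(0, (int)j));
      mult[j] = P.mult[i]; adj[j] = P.adj[i]; part[j] = p;
      ++j;
    }
  }
  return List::create(_["code"] = code, _["multiplicity"] = mult,
                      _["adjacency"] = adj, _["partition"] = part);
}

// [[Rcpp::export]]
List cpp_store_lookup(SEXP sp, RawMatrix codes) {
  Store* S = get_store(sp);
  R_xlen_t n = codes.ncol();
  IntegerVector mult(n), adj(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    uint64_t x = raw_to_code(&codes(0, j));
    uint64_t c = std::min(x, rc_code(x, S->k));
    int p; long i = find_idx(*S, c, p);
    if (i < 0) { mult[j] = NA_INTEGER; adj[j] = NA_INTEGER; }
    else { mult[j] = S->parts[p].mult[i]; adj[j] = S->parts[p].adj[i]; }
  }
  return List::create(_["multiplicity"] = mult, _["adjacency"] = adj);
}

// Full linear scan over every partition slot: the reference for lookup tests.
// [[Rcpp::export]]
List cpp_store_lookup_linear(SEXP sp, RawMatrix codes) {
  Store* S = get_store(sp);
  R_xlen_t n = codes.ncol();
  IntegerVector mult(n), adj(n);
  for (R_xlen_t j = 0; j < n; ++j) {
    uint64_t x = raw_to_code(&codes(0, j));
    uint64_t c = std::min(x, rc_code(x, S->k));
    mult[j] = NA_INTEGER; adj[j] = NA_INTEGER;
    for (auto& P : S->parts)
      for (size_t i = 0; i < P.code.size(); ++i)
        if (!P.dead[i] && P.code[i] == c) { mult[j] = P.mult[i]; adj[j] = P.adj[i]; }
  }
  return List::create(_["multiplicity"] = mult, _["adjacency"] = adj);
}

// neighbour canonical code and the reciprocal adjacency bit for a set bit
static inline void neighbor_of(uint64_t c, int k, int bit, uint64_t& ncan,
                               int& rbit) {
  uint64_t mask = kmask(k);
  if (bit < 4) { // right-extension of the canonical strand by base `bit`
    uint64_t n = ((c << 2) | (uint64_t)bit) & mask;
    uint64_t rn = rc_code(n, k);
    int c0 = (int)((c >> (2 * (k - 1))) & 3);
    if (n <= rn) { ncan = n;  rbit = 4 + (3 - c0); }
    else         { ncan = rn; rbit = 3 - c0; }
  } else { // left-extension; preceding base is the complement of the index
    int a = 3 - (bit - 4);
    uint64_t n = ((uint64_t)a << (2 * (k - 1))) | (c >> 2);
    uint64_t rn = rc_code(n, k);
    int cl = (int)(c & 3);
    if (n <= rn) { ncan = n;  rbit = cl; }
    else         { ncan = rn; rbit = 4 + cl; }
  }
}

// tombstone a record and clear the bits of surviving neighbours that point at it
static void kill_record(Store& S, int p, size_t i) {
  Part& P = S.parts[p];
  if (P.dead[i]) return;
  uint8_t adj = P.adj[i];
  uint64_t c = P.code[i];
  P.adj[i] = 0;
  P.dead[i] = 1;
  for (int bit = 0; bit < 8; ++bit) {
    if (!(adj & (1 << bit))) continue;
    uint64_t ncan; int rbit;
    neighbor_of(c, S.k, bit, ncan, rbit);
    int np; long ni = find_idx(S, ncan, np);
    if (ni >= 0) S.parts[np].adj[ni] &= (uint8_t)~(1 << rbit);
  }
}

// [[Rcpp::export]]
int cpp_store_remove(SEXP sp, RawMatrix codes, bool clear_neighbors) {
  Store* S = get_store(sp);
  int removed = 0;
  for (R_xlen_t j = 0; j < codes.ncol(); ++j) {
    uint64_t x = raw_to_code(&codes(0, j));
    uint64_t c = std::min(x, rc_code(x, S->k));
    int p; long i = find_idx(*S, c, p);
    if (i < 0) continue; // absent or already removed: no-op
    if (clear_neighbors) kill_record(*S, p, (size_t)i);
    else { S->parts[p].dead[i] = 1; S->parts[p].adj[i] = 0; }
    ++removed;
  }
  return removed;
}

// [[Rcpp::export]]
void cpp_store_compact(SEXP sp) {
  Store* S = get_store(sp);
  for (auto& P : S->parts) {
    size_t j = 0;
    for (size_t i = 0; i < P.code.size(); ++i) {
      if (P.dead[i]) continue;
      P.code[j] = P.code[i]; P.mult[j] = P.mult[i]; P.adj[j] = P.adj[i];
      ++j;
    }
    P.code.resize(j); P.mult.resize(j); P.adj.resize(j);
    P.dead.assign(j, 0);
    build_accel(P, 2 * S->k, S->reff);
  }
}

// [[Rcpp::export]]
void cpp_add_linkages(SEXP sp, CharacterVector reads) {
  Store* S = get_store(sp);
  int k = S->k;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  for (R_xlen_t rr = 0; rr < reads.size(); ++rr) {
    const char* s = CHAR(STRING_ELT(reads, rr));
    int len = (int)std::strlen(s);
    uint64_t f = 0, r = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (i < k - 1) continue;
      int j = i - k + 1; // k-mer occupies [j, j + k - 1]
      bool fwd = (f <= r);
      uint64_t c = fwd ? f : r;
      int p; long idx = find_idx(*S, c, p);
      if (idx < 0)
        stop("k-mer at read %d position %d is absent from the store; "
             "linkage construction must see the same reads as counting",
             (int)rr + 1, j + 1);
      uint8_t bits = 0;
      int a = (j > 0) ? base_code(s[j - 1]) : -1;
      int bnext = (j + k < len) ? base_code(s[j + k]) : -1;
      if (fwd) {
        if (bnext >= 0) bits |= (uint8_t)(1 << bnext);
        if (a >= 0)     bits |= (uint8_t)(1 << (4 + (3 - a)));
      } else {
        if (bnext >= 0) bits |= (uint8_t)(1 << (4 + bnext));
        if (a >= 0)     bits |= (uint8_t)(1 << (3 - a));
      }
      S->parts[p].adj[idx] |= bits;
    }
  }
}

// [[Rcpp::export]]
IntegerVector cpp_store_mults(SEXP sp) {
  Store* S = get_store(sp);
  std::vector<int> v;
  for (auto& P : S->parts)
    for (size_t i = 0; i < P.code.size(); ++i)
      if (!P.dead[i]) v.push_back(P.mult[i]);
  return wrap(v);
}

// check: every set adjacency bit has its reciprocal bit set on the neighbour
// [[Rcpp::export]]
bool cpp_check_edge_symmetry(SEXP sp) {
  Store* S = get_store(sp);
  for (int p = 0; p < S->nparts; ++p) {
    Part& P = S->parts[p];
    for (size_t i = 0; i < P.code.size(); ++i) {
      if (P.dead[i]) continue;
      for (int bit = 0; bit < 8; ++bit) {
        if (!(P.adj[i] & (1 << bit))) continue;
        uint64_t ncan; int rbit;
        neighbor_of(P.code[i], S->k, bit, ncan, rbit);
        int np; long ni = find_idx(*S, ncan, np);
        if (ni < 0) return false;
        if (!(S->parts[np].adj[ni] & (1 << rbit))) return false;
      }
    }
  }
  return true;
}

// --------------------------------------------------------- simplification

// round-by-round removal of dead-end k-mers with multiplicity < M
// [[Rcpp::export]]
List cpp_remove_low_freq_dead_ends(SEXP sp, int M) {
  Store* S = get_store(sp);
  int total = 0, rounds = 0;
  for (;;) {
    std::vector<std::pair<int, size_t>> cand;
    for (int p = 0; p < S->nparts; ++p) {
      Part& P = S->parts[p];
      for (size_t i = 0; i < P.code.size(); ++i) {
        if (P.dead[i] || P.mult[i] >= M) continue;
        int rd = pc4(P.adj[i] & 0xF), ld = pc4(P.adj[i] >> 4);
        if (rd == 0 || ld == 0) cand.push_back({p, i});
      }
    }
    if (cand.empty()) break;
    ++rounds;
    for (auto& c : cand) kill_record(*S, c.first, c.second);
    total += (int)cand.size();
  }
  return List::create(_["removed"] = total, _["rounds"] = rounds);
}

struct Cursor { int p; long i; int o; uint64_t c; };

static inline uint8_t cur_adj(const Store& S, const Cursor& u) {
  return S.parts[u.p].adj[u.i];
}
static inline int out_nib(uint8_t adj, int o) { return o > 0 ? (adj & 0xF) : (adj >> 4); }
static inline int in_nib(uint8_t adj, int o)  { return o > 0 ? (adj >> 4) : (adj & 0xF); }

// advance one unitig-compaction step: requires out-degree 1 at the cursor and
// in-degree 1 at the successor; returns the appended base on success
static bool advance(const Store& S, Cursor& u, int& base_out) {
  uint8_t adj = cur_adj(S, u);
  int on = out_nib(adj, u.o);
  if (pc4(on) != 1) return false;
  int x = 0; while (!(on & (1 << x))) ++x;
  uint64_t obs = u.o > 0 ? u.c : rc_code(u.c, S.k);
  uint64_t n = ((obs << 2) | (uint64_t)x) & kmask(S.k);
  uint64_t rn = rc_code(n, S.k);
  uint64_t ncan = std::min(n, rn);
  int no = (n == ncan) ? 1 : -1;
  int np; long ni = find_idx(S, ncan, np);
  if (ni < 0) return false;
  // a step onto the record we stand on is a hairpin fold (the successor is
  // the reverse complement of the current k-mer) or a unit self-loop; the
  // chain terminates rather than re-traversing the k-molecule
  if (np == u.p && ni == u.i) return false;
  if (pc4(in_nib(S.parts[np].adj[ni], no)) != 1) return false;
  u.p = np; u.i = ni; u.o = no; u.c = ncan;
  base_out = x;
  return true;
}

// follow the single outgoing edge regardless of the successor's in-degree;
// used by tip walking, where we must see the junction node
static bool step_out(const Store& S, Cursor& u, int& indeg_next) {
  uint8_t adj = cur_adj(S, u);
  int on = out_nib(adj, u.o);
  if (pc4(on) != 1) return false;
  int x = 0; while (!(on & (1 << x))) ++x;
  uint64_t obs = u.o > 0 ? u.c : rc_code(u.c, S.k);
  uint64_t n = ((obs << 2) | (uint64_t)x) & kmask(S.k);
  uint64_t rn = rc_code(n, S.k);
  uint64_t ncan = std::min(n, rn);
  int no = (n == ncan) ? 1 : -1;
  int np; long ni = find_idx(S, ncan, np);
  if (ni < 0) return false;
  if (np == u.p && ni == u.i) return false; // hairpin fold / self-loop
  indeg_next = pc4(in_nib(S.parts[np].adj[ni], no));
  u.p = np; u.i = ni; u.o = no; u.c = ncan;
  return true;
}

// iterative removal of tips (< 2k bases, attached to a branching node)
// [[Rcpp::export]]
List cpp_remove_tips(SEXP sp) {
  Store* S = get_store(sp);
  int k = S->k;
  int chains_removed = 0, kmers_removed = 0, rounds = 0;
  bool changed = true;
  while (changed) {
    changed = false; ++rounds;
    for (int p = 0; p < S->nparts; ++p) {
      Part& P = S->parts[p];
      for (size_t i = 0; i < P.code.size(); ++i) {
        if (P.dead[i]) continue;
        uint8_t adj = P.adj[i];
        int rd = pc4(adj & 0xF), ld = pc4(adj >> 4);
        if (ld == 0 && rd == 0) continue;    // isolated node: not a tip
        int o;
        if (ld == 0) o = 1; else if (rd == 0) o = -1; else continue;
        // walk away from the dead end; tip removable iff it ends at a
        // branching node and spans < 2k bases (<= k k-mers)
        std::vector<std::pair<int, size_t>> chain;
        Cursor u{p, (long)i, o, P.code[i]};
        bool tip = false;
        for (;;) {
          chain.push_back({u.p, (size_t)u.i});
          if ((int)chain.size() > k) break; // >= 2k bases: released
          uint8_t ca = cur_adj(*S, u);
          int od = pc4(out_nib(ca, u.o));
          if (od == 0) break;                // isolated linear chain: kept
          if (od >= 2) { chain.pop_back(); tip = !chain.empty(); break; }
          Cursor v = u; int indeg = 0;
          if (!step_out(*S, v, indeg)) break;
          if (indeg >= 2) { tip = true; break; } // v is the junction, kept
          bool cyc = false;
          for (auto& c : chain)
            if (c.first == v.p && c.second == (size_t)v.i) { cyc = true; break; }
          if (cyc) break;
          u = v;
        }
        if (tip && (int)chain.size() <= k) {
          for (auto& c : chain) kill_record(*S, c.first, c.second);
          ++chains_removed;
          kmers_removed += (int)chain.size();
          changed = true;
        }
      }
    }
  }
  return List::create(_["tips_removed"] = chains_removed,
                      _["kmers_removed"] = kmers_removed,
                      _["rounds"] = rounds);
}

// ------------------------------------------------------- chain extraction

static std::string walk_sequence(const Store& S, Cursor u, long steps,
                                 double& mult_sum) {
  std::string seq = decode_str(u.o > 0 ? u.c : rc_code(u.c, S.k), S.k);
  mult_sum = (double)S.parts[u.p].mult[u.i];
  for (long t = 0; t < steps; ++t) {
    int x;
    if (!advance(S, u, x)) stop("internal error: chain walk broke");
    seq.push_back(code_base(x));
    mult_sum += (double)S.parts[u.p].mult[u.i];
  }
  return seq;
}

// Two-step linear-chain extraction. Step 1 walks from every dead-end k-mer;
// when the far terminal is also a dead end a rival walk exists, and the chain
// is kept only by the walk whose start partition is <= the far partition
// (ties broken by the smaller terminal code). Step 2 walks remaining k-mers
// in both directions; cycles are broken at the smallest canonical code and
// emitted in the direction giving the smaller sequence, so output does not
// depend on the partition count.
// [[Rcpp::export]]
List cpp_extract_chains(SEXP sp) {
  Store* S = get_store(sp);
  int k = S->k;
  std::vector<std::vector<uint8_t>> claimed(S->nparts);
  for (int p = 0; p < S->nparts; ++p)
    claimed[p].assign(S->parts[p].code.size(), 0);

  std::vector<std::string> seqs;
  std::vector<double> kcnt, msum;

  // ---- step 1: from dead ends
  for (int p = 0; p < S->nparts; ++p) {
    Part& P = S->parts[p];
    for (size_t i = 0; i < P.code.size(); ++i) {
      if (P.dead[i]) continue;
      uint8_t adj = P.adj[i];
      int rd = pc4(adj & 0xF), ld = pc4(adj >> 4);
      if (ld != 0 && rd != 0) continue;
      if (ld == 0 && rd == 0) { // isolated single k-mer
        if (!claimed[p][i]) {
          claimed[p][i] = 1;
          seqs.push_back(decode_str(P.code[i], k));
          kcnt.push_back(1);
          msum.push_back((double)P.mult[i]);
        }
        continue;
      }
      int o = (ld == 0) ? 1 : -1;
      Cursor u{p, (long)i, o, P.code[i]};
      Cursor start = u;
      long steps = 0;
      claimed[u.p][u.i] = 1;
      int x;
      while (advance(*S, u, x)) { claimed[u.p][u.i] = 1; ++steps; }
      // decide emission
      uint8_t la = cur_adj(*S, u);
      int od = pc4(out_nib(la, u.o));
      bool emit;
      if (od == 0) { // far terminal is a dead end: rival walk exists there
        int pi = start.p, pj = u.p;
        emit = (pi < pj) || (pi == pj && start.c < u.c) ||
               (start.p == u.p && start.i == u.i);
      } else {
        emit = true; // stopped by a junction; no rival walk
      }
      if (emit) {
        double ms;
        std::string s = walk_sequence(*S, start, steps, ms);
        seqs.push_back(s);
        kcnt.push_back((double)(steps + 1));
        msum.push_back(ms);
      }
    }
  }

  // ---- step 2: remaining k-mers (between-junction chains and cycles)
  for (int p = 0; p < S->nparts; ++p) {
    Part& P = S->parts[p];
    for (size_t i = 0; i < P.code.size(); ++i) {
      if (P.dead[i] || claimed[p][i]) continue;
      Cursor start{p, (long)i, 1, P.code[i]};
      claimed[p][i] = 1;
      // forward extension with cycle detection
      std::vector<Cursor> nodes{start};
      Cursor u = start;
      bool cycle = false;
      int x;
      for (;;) {
        Cursor v = u;
        if (!advance(*S, v, x)) break;
        if (v.p == start.p && v.i == start.i) { cycle = true; break; }
        claimed[v.p][v.i] = 1;
        nodes.push_back(v);
        u = v;
      }
      double ms = 0;
      for (auto& nd : nodes) ms += (double)S->parts[nd.p].mult[nd.i];
      if (cycle) {
        // rotate to the smallest canonical code; emit the direction whose
        // sequence is lexicographically smaller
        size_t mi = 0;
        for (size_t t = 1; t < nodes.size(); ++t)
          if (nodes[t].c < nodes[mi].c) mi = t;
        long m = (long)nodes.size();
        Cursor fwd = nodes[mi];
        Cursor bwd = nodes[mi]; bwd.o = -bwd.o;
        double d1, d2;
        std::string s1 = walk_sequence(*S, fwd, m - 1, d1);
        std::string s2 = walk_sequence(*S, bwd, m - 1, d2);
        seqs.push_back(std::min(s1, s2));
        kcnt.push_back((double)m);
        msum.push_back(ms);
      } else {
        // backward extension from the start node
        Cursor b = start; b.o = -b.o;
        long back = 0;
        for (;;) {
          Cursor v = b;
          if (!advance(*S, v, x)) break;
          claimed[v.p][v.i] = 1;
          b = v; ++back;
        }
        Cursor origin = b; origin.o = -origin.o; // leftmost, facing forward
        long steps = back + (long)nodes.size() - 1;
        double d;
        std::string s = walk_sequence(*S, origin, steps, d);
        seqs.push_back(s);
        kcnt.push_back((double)(steps + 1));
        msum.push_back(d);
      }
    }
  }

  // canonical strand presentation
  for (auto& s : seqs) {
    std::string r = revcomp_str(s);
    if (r < s) s = r;
  }
  return List::create(_["sequence"] = wrap(seqs), _["kmer_count"] = wrap(kcnt),
                      _["mult_sum"] = wrap(msum));
}

// ------------------------------------------------------------ .pshk files

static void put_u64(std::ofstream& f, uint64_t x) {
  char b[8];
  for (int i = 0; i < 8; ++i) { b[i] = (char)(x & 0xFF); x >>= 8; }
  f.write(b, 8);
}

// [[Rcpp::export]]
void cpp_write_pshk(SEXP sp, int part, std::string path) {
  Store* S = get_store(sp);
  if (part < 0 || part >= S->nparts) stop("partition index out of range");
  Part& P = S->parts[part];
  std::ofstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  uint64_t n = 0;
  for (size_t i = 0; i < P.code.size(); ++i) if (!P.dead[i]) ++n;
  f.write("PSHK", 4);
  char ver = 1, kk = (char)S->k, rr = (char)S->rbits;
  f.write(&ver, 1); f.write(&kk, 1); f.write(&rr, 1);
  put_u64(f, n);
  for (size_t i = 0; i < P.code.size(); ++i) {
    if (P.dead[i]) continue;
    put_u64(f, P.code[i]);
    char m[2] = {(char)(P.mult[i] & 0xFF), (char)((P.mult[i] >> 8) & 0xFF)};
    f.write(m, 2);
    char a = (char)P.adj[i];
    f.write(&a, 1);
  }
  if (!f) stop("write to '%s' failed", path.c_str());
}

// [[Rcpp::export]]
List cpp_read_pshk(std::string path) {
  std::ifstream f(path.c_str(), std::ios::binary);
  if (!f) stop("cannot open '%s'", path.c_str());
  char hdr[7];
  f.read(hdr, 7);
  if (f.gcount() != 7) stop("'%s': truncated header at offset %d",
                            path.c_str(), (int)f.gcount());
  if (std::memcmp(hdr, "PSHK", 4) != 0)
    stop("'%s': bad magic at offset 0 (not a k-mer partition file)", path.c_str());
  if (hdr[4] != 1)
    stop("'%s': unsupported format version %d at offset 4", path.c_str(), (int)hdr[4]);
  int k = (int)(unsigned char)hdr[5], r = (int)(unsigned char)hdr[6];
  char nb[8];
  f.read(nb, 8);
  if (f.gcount() != 8) stop("'%s': truncated record count at offset 7", path.c_str());
  uint64_t n = 0;
  for (int i = 7; i >= 0; --i) n = (n << 8) | (uint64_t)(unsigned char)nb[i];
  RawMatrix code(8, (int)n);
  IntegerVector mult((int)n), adj((int)n);
  std::vector<char> rec(11);
  for (uint64_t j = 0; j < n; ++j) {
    f.read(rec.data(), 11);
    if (f.gcount() != 11)
      stop("'%s': truncated record %d at offset %d", path.c_str(), (int)j + 1,
           (int)(15 + 11 * j + f.gcount()));
    for (int i = 0; i < 8; ++i) code(i, (int)j) = (Rbyte)rec[i];
    mult[j] = (int)(unsigned char)rec[8] | ((int)(unsigned char)rec[9] << 8);
    adj[j] = (int)(unsigned char)rec[10];
  }
  return List::create(_["k"] = k, _["r"] = r, _["code"] = code,
                      _["multiplicity"] = mult, _["adjacency"] = adj);
}

// ------------------------------------------- read-to-node map (stages iii/iv)

struct NodeHit { int32_t node; int32_t pos; int8_t strand; };

struct NodeMap {
  int k;
  std::unordered_map<uint64_t, NodeHit> m;
  std::unordered_set<uint64_t> ambig;
};

// [[Rcpp::export]]
SEXP cpp_build_node_map(CharacterVector seqs, int k) {
  XPtr<NodeMap> ptr(new NodeMap(), true);
  NodeMap* M = ptr.get();
  M->k = k;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  for (R_xlen_t j = 0; j < seqs.size(); ++j) {
    const char* s = CHAR(STRING_ELT(seqs, j));
    int len = (int)std::strlen(s);
    uint64_t f = 0, r = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (i < k - 1) continue;
      uint64_t c = std::min(f, r);
      if (M->ambig.count(c)) continue;
      auto it = M->m.find(c);
      if (it != M->m.end()) { M->m.erase(it); M->ambig.insert(c); continue; }
      NodeHit h;
      h.node = (int32_t)j + 1;
      h.pos = i - k + 1;
      h.strand = (f <= r) ? 1 : -1; // node forward k-mer == canonical?
      M->m[c] = h;
    }
  }
  return ptr;
}

// Thread reads through the node map: consecutive k-mers landing on two
// different nodes create/update a directed edge between oriented nodes.
// Edges are normalized with their twins ((u,v) == (-v,-u)).
// [[Rcpp::export]]
List cpp_thread_reads(SEXP mp, CharacterVector reads) {
  XPtr<NodeMap> M(mp);
  int k = M->k;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  std::map<std::pair<int, int>, int> edges;
  for (R_xlen_t rr = 0; rr < reads.size(); ++rr) {
    const char* s = CHAR(STRING_ELT(reads, rr));
    int len = (int)std::strlen(s);
    uint64_t f = 0, r = 0;
    int prev = 0; // signed node of previous k-mer, 0 = unmapped
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (i < k - 1) continue;
      uint64_t c = std::min(f, r);
      int curr = 0;
      auto it = M->m.find(c);
      if (it != M->m.end()) {
        int os = (f <= r) ? 1 : -1;
        curr = it->second.node * os * it->second.strand;
      }
      if (prev != 0 && curr != 0 && std::abs(prev) != std::abs(curr)) {
        std::pair<int, int> e{prev, curr}, tw{-curr, -prev};
        if (tw < e) e = tw;
        edges[e]++;
      }
      prev = curr;
    }
  }
  int n = (int)edges.size();
  IntegerVector from(n), to(n), support(n);
  int j = 0;
  for (auto& kv : edges) {
    from[j] = kv.first.first; to[j] = kv.first.second; support[j] = kv.second;
    ++j;
  }
  return List::create(_["from"] = from, _["to"] = to, _["support"] = support);
}

// Map whole reads to nodes: a read maps iff >= min_frac of its k-mers hit one
// node at one consistent diagonal; ties (two equally supported placements)
// are treated as ambiguous and dropped.
// [[Rcpp::export]]
List cpp_map_reads(SEXP mp, CharacterVector reads, double min_frac) {
  XPtr<NodeMap> M(mp);
  int k = M->k;
  uint64_t mask = kmask(k);
  int shift = 2 * (k - 1);
  R_xlen_t n = reads.size();
  IntegerVector node(n), start(n);
  IntegerVector strand(n);
  NumericVector frac(n);
  for (R_xlen_t rr = 0; rr < n; ++rr) {
    node[rr] = NA_INTEGER; strand[rr] = NA_INTEGER; start[rr] = NA_INTEGER;
    frac[rr] = 0.0;
    const char* s = CHAR(STRING_ELT(reads, rr));
    int len = (int)std::strlen(s);
    if (len < k) continue;
    int nk = len - k + 1;
    std::map<std::tuple<int, int, int>, int> votes; // (node, dir, diagonal)
    uint64_t f = 0, r = 0;
    for (int i = 0; i < len; ++i) {
      int b = base_code(s[i]);
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (i < k - 1) continue;
      int j = i - k + 1;
      uint64_t c = std::min(f, r);
      auto it = M->m.find(c);
      if (it == M->m.end()) continue;
      int os = (f <= r) ? 1 : -1;
      int dir = os * it->second.strand;
      int c0 = (dir > 0) ? (it->second.pos - j) : (it->second.pos + j);
      votes[std::make_tuple((int)it->second.node, dir, c0)]++;
    }
    if (votes.empty()) continue;
    int best = 0, nbest = 0;
    std::tuple<int, int, int> bkey;
    for (auto& kv : votes) {
      if (kv.second > best) { best = kv.second; nbest = 1; bkey = kv.first; }
      else if (kv.second == best) ++nbest;
    }
    frac[rr] = (double)best / (double)nk;
    if (nbest > 1) continue;                       // ambiguous placement
    if ((double)best < min_frac * (double)nk) continue;
    int nd = std::get<0>(bkey), dir = std::get<1>(bkey), c0 = std::get<2>(bkey);
    node[rr] = nd;
    strand[rr] = dir;
    start[rr] = (dir > 0) ? c0 : (c0 + k - len);  // leftmost 0-based coord
  }
  return List::create(_["node"] = node, _["strand"] = strand,
                      _["start"] = start, _["frac"] = frac);
}
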