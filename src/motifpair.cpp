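// Core machinery for planted (l,d) motif search: 2-bit l-mer codes,
// byte-table Hamming distance, ball-intersection traversal, filtering
// rules and the pair-driven search engine, plus a 4^l brute-force oracle.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <string>
#include <vector>
#include <algorithm>
#include <functional>
#include <unordered_set>

using namespace Rcpp;

namespace {

const char BASES[4] = {'A', 'C', 'G', 'T'};

// A=00, C=01, G=10, T=11; base i of the word occupies bits [2i, 2i+1]
inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

// 256-entry table: number of non-00 2-bit fields in a byte (4 base positions)
struct ByteTable {
  int cnt[256];
  ByteTable() {
    for (int b = 0; b < 256; ++b) {
      int c = 0;
      for (int j = 0; j < 4; ++j)
        if ((b >> (2 * j)) & 3) ++c;
      cnt[b] = c;
    }
  }
};
const ByteTable BT;

// XOR then ceil(l/4) byte lookups; high padding bits XOR to 00
inline int ham_code(uint64_t a, uint64_t b, int l) {
  uint64_t x = a ^ b;
  int d = 0;
  int nb = (l + 3) / 4;
  for (int i = 0; i < nb; ++i) {
    d += BT.cnt[x & 0xFFu];
    x >>= 8;
  }
  return d;
}

inline uint64_t get_base(uint64_t w, int pos) { return (w >> (2 * pos)) & 3; }
inline void set_base(uint64_t& w, int pos, uint64_t c) {
  w = (w & ~((uint64_t)3 << (2 * pos))) | (c << (2 * pos));
}

// returns false and sets bad to the 0-based offending position on failure
inline bool encode_str(const std::string& w, uint64_t& code, int& bad) {
  code = 0;
  for (size_t i = 0; i < w.size(); ++i) {
    int c = base_code(w[i]);
    if (c < 0) { bad = (int)i; return false; }
    code |= (uint64_t)c << (2 * i);
  }
  bad = -1;
  return true;
}

inline std::string decode_code(uint64_t code, int l) {
  std::string w(l, 'A');
  for (int i = 0; i < l; ++i) w[i] = BASES[get_base(code, i)];
  return w;
}

inline uint64_t must_encode(const std::string& w, const char* what) {
  uint64_t code; int bad;
  if ((int)w.size() > 32)
    stop("%s longer than 32 bases is not supported", what);
  if (!encode_str(w, code, bad))
    stop("invalid character '%c' in %s at position %d (expected A/C/G/T)",
         w[bad], what, bad + 1);
  return code;
}

// ---- deterministic traversal of M_d(x, x') ------------------------------
//
// For each admissible (alpha, beta) signature, start from y = x' and
// (1) flip alpha matched positions to one of the 3 non-x bases,
// (2) flip beta mismatched positions to one of the 2 bases differing from
//     both x and x',
// (3) reset k of the remaining mismatched positions to x's base, with k
//     constrained so d_H(y,x) <= d and d_H(y,x') <= d.
// Order: (alpha, beta) lexicographic, then step-1/step-2 position subsets
// and substitution bases ascending, then k ascending with step-3 subsets
// ascending — fixed so runs are reproducible.
class MdEnumerator {
public:
  MdEnumerator(uint64_t xc, uint64_t pc, int l, int d,
               std::function<void(uint64_t)> emit)
      : xc_(xc), pc_(pc), l_(l), d_(d), emit_(emit) {}

  void run() {
    h_ = ham_code(xc_, pc_, l_);
    if (h_ > 2 * d_) return;
    P1_.clear(); P0_.clear();
    for (int i = 0; i < l_; ++i) {
      if (get_base(xc_, i) == get_base(pc_, i)) P1_.push_back(i);
      else P0_.push_back(i);
    }
    used_.assign(P0_.size(), false);
    for (a_ = 0; a_ <= l_ - h_; ++a_) {
      for (b_ = 0; b_ <= h_; ++b_) {
        if (2 * a_ + b_ + h_ > 2 * d_) continue;
        y_ = pc_;
        step1(0, a_);
      }
    }
  }

private:
  void step1(int start, int remaining) {
    if (remaining == 0) { step2(0, b_); return; }
    for (int i = start; i <= (int)P1_.size() - remaining; ++i) {
      int pos = P1_[i];
      uint64_t xb = get_base(xc_, pos);
      for (uint64_t c = 0; c < 4; ++c) {
        if (c == xb) continue;
        set_base(y_, pos, c);
        step1(i + 1, remaining - 1);
      }
      set_base(y_, pos, xb);
    }
  }

  void step2(int start, int remaining) {
    if (remaining == 0) { step3(); return; }
    for (int i = start; i <= (int)P0_.size() - remaining; ++i) {
      int pos = P0_[i];
      uint64_t xb = get_base(xc_, pos), pb = get_base(pc_, pos);
      used_[i] = true;
      for (uint64_t c = 0; c < 4; ++c) {
        if (c == xb || c == pb) continue;
        set_base(y_, pos, c);
        step2(i + 1, remaining - 1);
      }
      set_base(y_, pos, pb);
      used_[i] = false;
    }
  }

  void step3() {
    rem_.clear();
    for (size_t i = 0; i < P0_.size(); ++i)
      if (!used_[i]) rem_.push_back(P0_[i]);
    int klo = std::max(0, a_ + h_ - d_);
    int khi = std::min((int)rem_.size(), d_ - a_ - b_);
    for (int k = klo; k <= khi; ++k) choose3(0, k);
  }

  void choose3(int start, int k) {
    if (k == 0) { emit_(y_); return; }
    for (int i = start; i <= (int)rem_.size() - k; ++i) {
      int pos = rem_[i];
      set_base(y_, pos, get_base(xc_, pos));
      choose3(i + 1, k - 1);
      set_base(y_, pos, get_base(pc_, pos));
    }
  }

  uint64_t xc_, pc_;
  int l_, d_, h_, a_, b_;
  std::function<void(uint64_t)> emit_;
  std::vector<int> P1_, P0_, rem_;
  std::vector<bool> used_;
  uint64_t y_;
};

// all valid l-windows of a sequence (windows containing non-ACGT are skipped)
struct SeqWindows {
  std::vector<uint64_t> code;
  std::vector<int> pos;  // 0-based
  int skipped;
};

SeqWindows windows_of(const std::string& s, int l) {
  SeqWindows w;
  w.skipped = 0;
  int n = (int)s.size();
  if (n < l) return w;
  std::vector<int> bc(n);
  for (int i = 0; i < n; ++i) bc[i] = base_code(s[i]);
  for (int p = 0; p + l <= n; ++p) {
    uint64_t code = 0;
    bool ok = true;
    for (int j = 0; j < l; ++j) {
      if (bc[p + j] < 0) { ok = false; break; }
      code |= (uint64_t)bc[p + j] << (2 * j);
    }
    if (ok) { w.code.push_back(code); w.pos.push_back(p); }
    else ++w.skipped;
  }
  return w;
}

// (p10, p00) of the alignment of x, x' and z
inline void p10_p00(uint64_t xc, uint64_t pc, uint64_t zc, int l,
                    int& p10, int& p00) {
  p10 = 0; p00 = 0;
  for (int i = 0; i < l; ++i) {
    uint64_t xb = get_base(xc, i), pb = get_base(pc, i), zb = get_base(zc, i);
    if (xb == pb) { if (zb != xb) ++p10; }
    else          { if (zb != xb && zb != pb) ++p00; }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_encode(CharacterVector words) {
  R_xlen_t n = words.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string w = as<std::string>(words[i]);
    if (w.size() > 26)
      stop("numeric codes are exact only up to l = 26; got l = %d", (int)w.size());
    out[i] = (double)must_encode(w, "l-mer");
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode(NumericVector codes, int l) {
  R_xlen_t n = codes.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double c = codes[i];
    if (c < 0 || c != std::floor(c)) stop("codes must be nonnegative integers");
    out[i] = decode_code((uint64_t)c, l);
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector x, CharacterVector y) {
  R_xlen_t nx = x.size(), ny = y.size();
  R_xlen_t n = std::max(nx, ny);
  if (n % std::min(nx, ny) != 0)
    stop("x and y lengths are not compatible for recycling");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string a = as<std::string>(x[i % nx]);
    std::string b = as<std::string>(y[i % ny]);
    if (a.size() != b.size())
      stop("words have different lengths (%d vs %d)", (int)a.size(), (int)b.size());
    uint64_t ac = must_encode(a, "word"), bc = must_encode(b, "word");
    out[i] = ham_code(ac, bc, (int)a.size());
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_partition(std::string x, std::string x_prime, std::string z) {
  if (x.size() != x_prime.size() || x.size() != z.size())
    stop("x, x_prime and z must have equal lengths");
  int l = (int)x.size();
  uint64_t xc = must_encode(x, "x"), pc = must_encode(x_prime, "x_prime"),
           zc = must_encode(z, "z");
  int p11 = 0, p10 = 0, p01 = 0, p00 = 0;
  for (int i = 0; i < l; ++i) {
    uint64_t xb = get_base(xc, i), pb = get_base(pc, i), zb = get_base(zc, i);
    if (xb == pb) { if (zb == xb) ++p11; else ++p10; }
    else          { if (zb == xb || zb == pb) ++p01; else ++p00; }
  }
  return IntegerVector::create(_["p11"] = p11, _["p10"] = p10,
                               _["p01"] = p01, _["p00"] = p00);
}

// [[Rcpp::export]]
CharacterVector cpp_enumerate(std::string x, std::string x_prime, int d) {
  if (x.size() != x_prime.size())
    stop("x and x_prime must have equal lengths");
  int l = (int)x.size();
  uint64_t xc = must_encode(x, "x"), pc = must_encode(x_prime, "x_prime");
  std::vector<std::string> out;
  MdEnumerator en(xc, pc, l, d,
                  [&](uint64_t y) { out.push_back(decode_code(y, l)); });
  en.run();
  return wrap(out);
}

// [[Rcpp::export]]
List cpp_scan(std::string x, std::string s, int maxdist) {
  int l = (int)x.size();
  uint64_t xc = must_encode(x, "x");
  SeqWindows w = windows_of(s, l);
  std::vector<int> pos, dist;
  std::vector<std::string> lmer;
  for (size_t i = 0; i < w.code.size(); ++i) {
    int d = ham_code(xc, w.code[i], l);
    if (d <= maxdist) {
      pos.push_back(w.pos[i]);
      dist.push_back(d);
      lmer.push_back(decode_code(w.code[i], l));
    }
  }
  return List::create(_["position"] = pos, _["lmer"] = lmer,
                      _["distance"] = dist, _["skipped"] = w.skipped);
}

// leftmost window of s minimizing d_H to x: c(position, distance), or c(-1, NA)
// [[Rcpp::export]]
IntegerVector cpp_best_window(std::string x, std::string s) {
  int l = (int)x.size();
  uint64_t xc = must_encode(x, "x");
  SeqWindows w = windows_of(s, l);
  int best = -1, bestd = l + 1;
  for (size_t i = 0; i < w.code.size(); ++i) {
    int d = ham_code(xc, w.code[i], l);
    if (d < bestd) { bestd = d; best = w.pos[i]; }
  }
  if (best < 0) return IntegerVector::create(-1, NA_INTEGER);
  return IntegerVector::create(best, bestd);
}

// The pair-driven search engine. `counts` is the cached per-h candidate
// count table (h = 0..2d) used for reference-sequence selection.
// [[Rcpp::export]]
List cpp_pair_search(CharacterVector seqs, int l, int d, NumericVector counts) {
  int t = (int)seqs.size();
  if (t < 2) stop("at least two sequences are required");
  if ((int)counts.size() != 2 * d + 1)
    stop("counts must have length 2d + 1");

  std::vector<SeqWindows> W(t);
  int skipped = 0;
  for (int i = 0; i < t; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < l)
      stop("sequence %d is shorter than l = %d", i + 1, l);
    W[i] = windows_of(s, l);
    skipped += W[i].skipped;
  }

  std::unordered_set<uint64_t> accepted, rejected, seen_x;

  // admissible (alpha, beta) signatures per pair distance h
  std::vector<std::vector<std::pair<int, int> > > rel(2 * d + 1);
  for (int h = 0; h <= 2 * d; ++h)
    for (int a = 0; a <= l - h; ++a)
      for (int b = 0; b <= h; ++b)
        if (2 * a + b + h <= 2 * d) rel[h].push_back(std::make_pair(a, b));

  std::vector<std::vector<uint64_t> > C(t);
  std::vector<std::vector<int> > Cd(t);
  std::vector<std::vector<uint64_t> > Cf(t);  // filtered survivors

  for (size_t xi = 0; xi < W[0].code.size(); ++xi) {
    Rcpp::checkUserInterrupt();
    uint64_t xc = W[0].code[xi];
    if (!seen_x.insert(xc).second) continue;  // distinct x strings only

    // C(x, s_i) for i = 2..t: windows within 2d of x
    bool any_empty = false;
    for (int i = 1; i < t; ++i) {
      C[i].clear(); Cd[i].clear();
      for (size_t j = 0; j < W[i].code.size(); ++j) {
        int dh = ham_code(xc, W[i].code[j], l);
        if (dh <= 2 * d) { C[i].push_back(W[i].code[j]); Cd[i].push_back(dh); }
      }
      if (C[i].empty()) { any_empty = true; break; }
    }
    if (any_empty) continue;

    // reference sequence: minimal summed candidate count, ties -> lowest index
    int r = 1;
    double best = -1.0;
    for (int i = 1; i < t; ++i) {
      double s = 0.0;
      for (size_t j = 0; j < Cd[i].size(); ++j) s += counts[Cd[i][j]];
      if (best < 0 || s < best) { best = s; r = i; }
    }

    std::unordered_set<uint64_t> seen_xp;
    for (size_t pi = 0; pi < C[r].size(); ++pi) {
      uint64_t pc = C[r][pi];
      if (!seen_xp.insert(pc).second) continue;
      int h = Cd[r][pi];
      const std::vector<std::pair<int, int> >& R = rel[h];

      // Rules 1 and 2 on C(x, s_i), i != r (Rule 1's d_H(z,x) <= 2d holds
      // already by construction of C)
      bool dead = false;
      for (int i = 1; i < t && !dead; ++i) {
        if (i == r) continue;
        Cf[i].clear();
        for (size_t j = 0; j < C[i].size(); ++j) {
          uint64_t zc = C[i][j];
          if (ham_code(zc, pc, l) > 2 * d) continue;  // Rule 1
          int p10, p00;
          p10_p00(xc, pc, zc, l, p10, p00);
          bool ok = false;                             // Rule 2
          for (size_t q = 0; q < R.size(); ++q) {
            if (std::abs(p10 - R[q].first) + std::abs(p00 - R[q].second) <= d) {
              ok = true; break;
            }
          }
          if (ok) Cf[i].push_back(zc);
        }
        if (Cf[i].empty()) dead = true;  // no candidate can verify
      }
      if (dead) continue;

      MdEnumerator en(xc, pc, l, d, [&](uint64_t y) {
        if (accepted.count(y) || rejected.count(y)) return;
        bool ok = true;
        for (int i = 1; i < t; ++i) {
          if (i == r) continue;
          bool found = false;
          const std::vector<uint64_t>& Z = Cf[i];
          for (size_t j = 0; j < Z.size(); ++j) {
            if (ham_code(y, Z[j], l) <= d) { found = true; break; }
          }
          if (!found) { ok = false; break; }
        }
        if (ok) accepted.insert(y); else rejected.insert(y);
      });
      en.run();
    }
  }

  std::vector<std::string> motifs;
  motifs.reserve(accepted.size());
  for (std::unordered_set<uint64_t>::const_iterator it = accepted.begin();
       it != accepted.end(); ++it)
    motifs.push_back(decode_code(*it, l));
  std::sort(motifs.begin(), motifs.end());
  return List::create(_["motifs"] = wrap(motifs), _["skipped"] = skipped);
}

// Definitional oracle: test every pattern in 4^l against every sequence.
// [[Rcpp::export]]
List cpp_brute_force(CharacterVector seqs, int l, int d) {
  if (l > 12) stop("brute force is guarded to l <= 12 (4^l patterns)");
  int t = (int)seqs.size();
  if (t < 1) stop("at least one sequence is required");
  std::vector<SeqWindows> W(t);
  int skipped = 0;
  for (int i = 0; i < t; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() < l)
      stop("sequence %d is shorter than l = %d", i + 1, l);
    W[i] = windows_of(s, l);
    skipped += W[i].skipped;
  }
  std::vector<std::string> motifs;
  uint64_t total = (uint64_t)1 << (2 * l);
  for (uint64_t m = 0; m < total; ++m) {
    if ((m & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    bool ok = true;
    for (int i = 0; i < t && ok; ++i) {
      bool found = false;
      const std::vector<uint64_t>& code = W[i].code;
      for (size_t j = 0; j < code.size(); ++j) {
        if (ham_code(m, code[j], l) <= d) { found = true; break; }
      }
      if (!found) ok = false;
    }
    if (ok) motifs.push_back(decode_code(m, l));
  }
  std::sort(motifs.begin(), motifs.end());
  return List::create(_["motifs"] = wrap(motifs), _["skipped"] = skipped);
}
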