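#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base2d(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// 64-row block step of Myers' bit-parallel automaton (see scan.cpp)
static inline int adv_block(uint64_t& Pv, uint64_t& Mv, uint64_t Eq, int hin) {
  const uint64_t HIGH = 0x8000000000000000ULL;
  uint64_t Xv = Eq | Mv;
  if (hin < 0) Eq |= 1ULL;
  uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
  uint64_t Ph = Mv | ~(Xh | Pv);
  uint64_t Mh = Pv & Xh;
  int hout = 0;
  if (Ph & HIGH) hout++;
  if (Mh & HIGH) hout--;
  Ph <<= 1;
  Mh <<= 1;
  if (hin < 0) Mh |= 1ULL;
  else if (hin > 0) Ph |= 1ULL;
  Pv = Mh | ~(Xv | Ph);
  Mv = Ph & Xv;
  return hout;
}

struct PatternMasks {
  int m, W, pad;
  std::vector<uint64_t> Peq;     // 4 x W
  std::vector<uint64_t> PadMask; // W
};

static void build_masks(const std::string& pat, PatternMasks& pm) {
  pm.m = (int) pat.size();
  pm.W = (pm.m + 63) / 64;
  pm.pad = pm.W * 64 - pm.m;
  pm.Peq.assign(4 * pm.W, 0);
  pm.PadMask.assign(pm.W, 0);
  for (int i = 0; i < pm.m; i++) {
    int c = base2d(pat[i]);
    if (c >= 0) pm.Peq[c * pm.W + i / 64] |= (1ULL << (i % 64));
  }
  for (int i = pm.m; i < pm.W * 64; i++) {
    pm.PadMask[i / 64] |= (1ULL << (i % 64));
    for (int c = 0; c < 4; c++) pm.Peq[c * pm.W + i / 64] |= (1ULL << (i % 64));
  }
}

// Global (Levenshtein) distance via blocked Myers.  The pattern is padded at
// the bottom with wildcard rows and the text with matching virtual columns;
// the padded global distance equals the true one.
static long long myers_global(const PatternMasks& pm, const std::string& text) {
  long long n = (long long) text.size();
  std::vector<uint64_t> Pv(pm.W, ~0ULL), Mv(pm.W, 0ULL);
  long long score = (long long) pm.W * 64;
  for (long long j = 0; j < n + pm.pad; j++) {
    int tc = (j < n) ? base2d(text[j]) : -2;
    int hin = 1; // global: top boundary D[0][j] = j
    for (int w = 0; w < pm.W; w++) {
      uint64_t Eq = (tc >= 0) ? pm.Peq[tc * pm.W + w] : pm.PadMask[w];
      hin = adv_block(Pv[w], Mv[w], Eq, hin);
    }
    score += hin;
  }
  return score;
}

// [[Rcpp::export]]
double levenshtein_cpp(const std::string& a, const std::string& b) {
  if (a.empty()) return (double) b.size();
  if (b.empty()) return (double) a.size();
  PatternMasks pm;
  build_masks(a, pm);
  return (double) myers_global(pm, b);
}

// Full symmetric Levenshtein matrix over a set of sequences.
// [[Rcpp::export]]
NumericMatrix levenshtein_matrix_cpp(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; i++) s[i] = as<std::string>(seqs[i]);
  NumericMatrix out(n, n);
  for (int i = 0; i < n; i++) {
    PatternMasks pm;
    build_masks(s[i], pm);
    for (int j = i + 1; j < n; j++) {
      double d = s[i].empty() ? (double) s[j].size() :
        (s[j].empty() ? (double) s[i].size() : (double) myers_global(pm, s[j]));
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
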