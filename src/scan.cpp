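#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

static inline int base2s(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1; // N (and any ambiguity code) never matches anything
  }
}

// one column step of Myers' bit-parallel edit-distance automaton for a
// 64-row block, with horizontal carries (Hyyro's block formulation)
static inline int advance_block(uint64_t& Pv, uint64_t& Mv, uint64_t Eq, int hin) {
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

// Semi-global (infix) edit-distance sweep: for every end position j of the
// text, the minimal unit-cost edit distance between the whole pattern and
// any text substring ending at j, capped at max_edits + 1.  Myers'
// bit-parallel algorithm over 64-row blocks; the pattern is padded at the
// bottom to a word multiple with wildcard rows, which (because adjacent
// end-distances differ by at most 1) shifts the end-distance profile right
// by the pad width without changing it, so the sweep runs `pad` virtual
// columns past the end of the text to recover the final positions exactly.
// Returns an integer vector of length nchar(text) (1-based ends).
// [[Rcpp::export]]
IntegerVector semiglobal_end_dists_cpp(const std::string& text, const std::string& pat,
                                       int max_edits) {
  int m = (int) pat.size();
  long long n = (long long) text.size();
  int k = max_edits;
  int inf = k + 1;
  if (m == 0) stop("empty pattern");
  IntegerVector out(n);
  int W = (m + 63) / 64;
  int pad = W * 64 - m;
  std::vector<uint64_t> Peq(4 * W, 0), PadMask(W, 0);
  for (int i = 0; i < m; i++) {
    int c = base2s(pat[i]);
    if (c >= 0) Peq[c * W + i / 64] |= (1ULL << (i % 64));
    // pattern N matches nothing: leave all Eq bits clear for that row
  }
  for (int i = m; i < W * 64; i++) { // wildcard padding rows match everything
    PadMask[i / 64] |= (1ULL << (i % 64));
    for (int c = 0; c < 4; c++) Peq[c * W + i / 64] |= (1ULL << (i % 64));
  }
  std::vector<uint64_t> Pv(W, ~0ULL), Mv(W, 0ULL);
  long long score = (long long) W * 64; // bottom-row distance at column 0
  for (long long j = 0; j < n + pad; j++) {
    int tc = (j < n) ? base2s(text[j]) : -2; // virtual tail columns
    int hin = 0;
    for (int w = 0; w < W; w++) {
      uint64_t Eq;
      if (tc >= 0) Eq = Peq[tc * W + w];
      else Eq = PadMask[w]; // N (or virtual char): only wildcard rows match
      hin = advance_block(Pv[w], Mv[w], Eq, hin);
    }
    score += hin;
    if (j >= pad) out[j - pad] = (score <= k) ? (int) score : inf;
  }
  return out;
}

// For each accepted end position (1-based, inclusive), recover the alignment
// start by a reverse semi-global DP of the reversed pattern against the
// reversed text suffix ending there.  Among spans achieving the minimal
// distance the span length closest to the pattern length wins, then the
// shorter span.  Returns (start, edits), 1-based.
// [[Rcpp::export]]
DataFrame locate_hit_starts_cpp(const std::string& text, const std::string& pat,
                                IntegerVector ends, int max_edits) {
  int m = (int) pat.size();
  long long n = (long long) text.size();
  int nh = ends.size();
  IntegerVector starts(nh), edits(nh);
  std::vector<int> pc(m);
  for (int i = 0; i < m; i++) pc[i] = base2s(pat[m - 1 - i]); // reversed pattern
  for (int h = 0; h < nh; h++) {
    long long e = ends[h]; // 1-based
    if (e < 1 || e > n) stop("end position out of range");
    int L = (int) std::min(e, (long long) (m + max_edits));
    // DP over reversed window text[e-1], text[e-2], ..., text[e-L]
    std::vector<int> D(m + 1), Dn(m + 1);
    for (int i = 0; i <= m; i++) D[i] = i;
    int bestd = D[m], bestl = 0;
    for (int l = 1; l <= L; l++) {
      int tc = base2s(text[e - l]);
      Dn[0] = 0;
      for (int i = 1; i <= m; i++) {
        int cost = (tc >= 0 && pc[i - 1] == tc) ? 0 : 1;
        int v = D[i - 1] + cost;
        int v2 = Dn[i - 1] + 1;
        if (v2 < v) v = v2;
        int v3 = D[i] + 1;
        if (v3 < v) v = v3;
        Dn[i] = v;
      }
      int d = Dn[m];
      if (d < bestd ||
          (d == bestd && std::abs(l - m) < std::abs(bestl - m)) ||
          (d == bestd && std::abs(l - m) == std::abs(bestl - m) && l < bestl)) {
        bestd = d;
        bestl = l;
      }
      std::swap(D, Dn);
    }
    starts[h] = (int) (e - bestl + 1);
    edits[h] = bestd;
  }
  return DataFrame::create(_["start"] = starts, _["end"] = ends, _["edits"] = edits);
}
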