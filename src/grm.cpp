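#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int base2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string decode_kmer(uint64_t code, int K) {
  static const char b[] = "ACGT";
  std::string s(K, 'A');
  for (int i = K - 1; i >= 0; i--) {
    s[i] = b[code & 3ULL];
    code >>= 2;
  }
  return s;
}

// Histogram of start-to-start distances between consecutive occurrences of
// every K-string (windows containing non-ACGT are skipped; distances above
// max_length are dropped).  Memory is bounded by the number of distinct
// K-strings present, so multi-Mb sequences stream in one pass.
// [[Rcpp::export]]
DataFrame kstring_histogram_cpp(const std::string& seq, int K, double max_length) {
  std::unordered_map<long long, double> hist;
  long long n = (long long) seq.size();
  if (n >= K && K >= 1 && K <= 32) {
    uint64_t code = 0;
    uint64_t mask = (K == 32) ? ~0ULL : ((1ULL << (2 * K)) - 1ULL);
    std::unordered_map<uint64_t, long long> last;
    last.reserve((size_t) std::min(n, (long long) 1 << 22));
    long long last_bad = -1;
    for (long long i = 0; i < n; i++) {
      int b = base2(seq[i]);
      if (b < 0) { last_bad = i; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      long long s = i - K + 1;
      if (s >= 0 && last_bad < s) {
        auto it = last.find(code);
        if (it == last.end()) {
          last.emplace(code, s);
        } else {
          long long d = s - it->second;
          if ((double) d <= max_length) hist[d] += 1.0;
          it->second = s;
        }
      }
    }
  } else if (n >= K) {
    // long K fallback: string keys
    std::unordered_map<std::string, long long> last;
    for (long long s = 0; s + K <= n; s++) {
      bool ok = true;
      for (int j = 0; j < K; j++) if (base2(seq[s + j]) < 0) { ok = false; break; }
      if (!ok) continue;
      std::string w = seq.substr(s, K);
      auto it = last.find(w);
      if (it == last.end()) {
        last.emplace(std::move(w), s);
      } else {
        long long d = s - it->second;
        if ((double) d <= max_length) hist[d] += 1.0;
        it->second = s;
      }
    }
  }
  std::vector<long long> lens;
  lens.reserve(hist.size());
  for (auto& kv : hist) lens.push_back(kv.first);
  std::sort(lens.begin(), lens.end());
  NumericVector L(lens.size()), C(lens.size());
  for (size_t i = 0; i < lens.size(); i++) { L[i] = (double) lens[i]; C[i] = hist[lens[i]]; }
  return DataFrame::create(_["length"] = L, _["count"] = C);
}

// Maximal runs of near-constant K-string recurrence: for every K-string with
// >= min_copies occurrences, consecutive-occurrence runs whose spacings all
// fall in [unit_min, unit_max] and whose spacing CV <= cv_max are emitted as
// candidate tandem regions (0-based start, end = last occurrence + modal unit).
// [[Rcpp::export]]
DataFrame kstring_tandem_runs_cpp(const std::string& seq, int K, int min_copies,
                                  double cv_max, double unit_min, double unit_max) {
  long long n = (long long) seq.size();
  if (K < 1 || K > 32) stop("tandem-run detection requires 1 <= K <= 32");
  uint64_t mask = (K == 32) ? ~0ULL : ((1ULL << (2 * K)) - 1ULL);

  // pass 1: occurrence counts
  std::unordered_map<uint64_t, int> cnt;
  {
    uint64_t code = 0;
    long long last_bad = -1;
    for (long long i = 0; i < n; i++) {
      int b = base2(seq[i]);
      if (b < 0) { last_bad = i; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      long long s = i - K + 1;
      if (s >= 0 && last_bad < s) cnt[code]++;
    }
  }
  // pass 2: positions for recurring K-strings only
  std::unordered_map<uint64_t, std::vector<long long> > occ;
  {
    uint64_t code = 0;
    long long last_bad = -1;
    for (long long i = 0; i < n; i++) {
      int b = base2(seq[i]);
      if (b < 0) { last_bad = i; continue; }
      code = ((code << 2) | (uint64_t) b) & mask;
      long long s = i - K + 1;
      if (s >= 0 && last_bad < s) {
        auto it = cnt.find(code);
        if (it != cnt.end() && it->second >= min_copies) occ[code].push_back(s);
      }
    }
  }
  std::vector<double> rs, re, runit, rn;
  std::vector<std::string> rkey;
  for (auto& kv : occ) {
    const std::vector<long long>& p = kv.second;
    size_t i = 0;
    while (i + 1 < p.size()) {
      size_t j = i;
      std::vector<long long> ds;
      while (j + 1 < p.size()) {
        long long d = p[j + 1] - p[j];
        if ((double) d < unit_min || (double) d > unit_max) break;
        ds.push_back(d);
        j++;
      }
      if ((long long) ds.size() >= (long long) min_copies - 1) {
        double mean = 0;
        for (auto d : ds) mean += (double) d;
        mean /= ds.size();
        double var = 0;
        for (auto d : ds) var += ((double) d - mean) * ((double) d - mean);
        var /= ds.size();
        double cv = std::sqrt(var) / mean;
        if (cv <= cv_max) {
          std::unordered_map<long long, int> c2;
          long long mode = ds[0];
          int best = 0;
          for (auto d : ds) {
            int c = ++c2[d];
            if (c > best || (c == best && d < mode)) { best = c; mode = d; }
          }
          rs.push_back((double) p[i]);
          re.push_back((double) (p[j] + mode));
          runit.push_back((double) mode);
          rn.push_back((double) ds.size() + 1);
          rkey.push_back(decode_kmer(kv.first, K));
        }
      }
      i = (j > i) ? j : i + 1;
    }
  }
  return DataFrame::create(_["start"] = rs, _["end"] = re, _["unit"] = runit,
                           _["n_units"] = rn, _["key"] = rkey,
                           _["stringsAsFactors"] = false);
}
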