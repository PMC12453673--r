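#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <climits>
#include <cstdint>
#include <cstdlib>
#include <string>
#include <thread>
#include <vector>

using namespace Rcpp;

namespace {

// 'N' is treated as an ambiguous base: it matches nothing, not even itself.
inline bool baseEq(char a, char b) { return a == b && a != 'N'; }

// base -> mask index; everything that is not A/C/G/T (including N) maps to -1
// and matches nothing.
inline int baseIdx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
  }
}

// Unit-cost Levenshtein distance, exact while <= cap; returns cap + 1 as soon
// as the band proves the true distance exceeds cap (Ukkonen banding: only
// cells with |i - j| <= cap can hold a value <= cap).
int levBanded(const std::string& a, const std::string& b, int cap) {
  const int la = (int)a.size(), lb = (int)b.size();
  if (cap < 0) cap = 0;
  if (std::abs(la - lb) > cap) return cap + 1;
  const int INF = cap + 1;
  if (la == 0) return lb;  // lb <= cap here
  if (lb == 0) return la;
  thread_local std::vector<int> prev, cur;
  prev.assign(lb + 1, INF);
  cur.assign(lb + 1, INF);
  for (int j = 0; j <= std::min(lb, cap); ++j) prev[j] = j;
  for (int i = 1; i <= la; ++i) {
    const int jlo = std::max(1, i - cap);
    const int jhi = std::min(lb, i + cap);
    cur[jlo - 1] = (jlo == 1 && i <= cap) ? i : INF;
    int rowMin = cur[jlo - 1];
    for (int j = jlo; j <= jhi; ++j) {
      int d = prev[j - 1] + (baseEq(a[i - 1], b[j - 1]) ? 0 : 1);
      if (prev[j] + 1 < d) d = prev[j] + 1;
      if (cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
      if (d > INF) d = INF;
      cur[j] = d;
      if (d < rowMin) rowMin = d;
    }
    if (jhi + 1 <= lb) cur[jhi + 1] = INF;  // seal band edge for next row
    if (rowMin >= INF) return INF;
    std::swap(prev, cur);
  }
  return prev[lb] > INF ? INF : prev[lb];
}

// Bit-parallel pattern masks for Myers' algorithm (patterns up to 64 bases).
struct PatternMasks {
  std::array<uint64_t, 4> eq;
  int len;
};

PatternMasks buildMasks(const std::string& p) {
  PatternMasks pm;
  pm.eq.fill(0);
  pm.len = (int)p.size();
  for (int i = 0; i < pm.len; ++i) {
    const int k = baseIdx(p[i]);
    if (k >= 0) pm.eq[k] |= (uint64_t)1 << i;
  }
  return pm;
}

// Myers/Hyyroe bit-parallel Levenshtein distance between a pattern (given by
// its precomputed masks) and a text. One word per text character; exact
// distance, no cap.
int levMyers(const PatternMasks& pm, const std::string& t) {
  const uint64_t highBit = (uint64_t)1 << (pm.len - 1);
  uint64_t Pv = ~(uint64_t)0, Mv = 0;
  int score = pm.len;
  for (char c : t) {
    const int k = baseIdx(c);
    const uint64_t Eq = (k >= 0) ? pm.eq[k] : 0;
    const uint64_t Xv = Eq | Mv;
    const uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
    uint64_t Ph = Mv | ~(Xh | Pv);
    uint64_t Mh = Pv & Xh;
    if (Ph & highBit) ++score;
    else if (Mh & highBit) --score;
    Ph = (Ph << 1) | 1;
    Mh <<= 1;
    Pv = Mh | ~(Xv | Ph);
    Mv = Ph & Xv;
  }
  return score;
}

// The 4-letter masks only model the A/C/G/T/N alphabet (N matches nothing);
// general strings must take the banded kernel.
inline bool isACGTN(const std::string& s) {
  for (char c : s)
    if (baseIdx(c) < 0 && c != 'N') return false;
  return true;
}

// Dispatch: exact distance while <= cap, cap + 1 otherwise.
int levCapped(const std::string& a, const std::string& b, int cap) {
  if (cap < 0) cap = 0;
  if (std::abs((int)a.size() - (int)b.size()) > cap) return cap + 1;
  if (!a.empty() && !b.empty() && a.size() <= 64 && isACGTN(a) &&
      isACGTN(b)) {
    const int d = levMyers(buildMasks(a), b);
    return d <= cap ? d : cap + 1;
  }
  return levBanded(a, b, cap);
}

// Pair threshold lookup by combined length of the two compared sequences.
inline int thrFor(const std::vector<int>& kmax, int n) {
  if (n < 0) n = 0;
  if (n >= (int)kmax.size()) n = (int)kmax.size() - 1;
  return kmax[n];
}

// Scan founders[from, to) in committed order, keeping the closest founder
// within its pair threshold. Strict improvement only (cap = bestd - 1), so the
// earliest founder wins ties, matching the producer's tie rule. Founder
// pattern masks are cached once per founder; sequences longer than 64 bases
// fall back to the banded kernel.
void scanFounders(const std::string& s, const std::vector<std::string>& seqs,
                  const std::vector<int>& founderRows,
                  const std::vector<PatternMasks>& founderMasks, int from,
                  int to, const std::vector<int>& kmax, int& best,
                  int& bestd) {
  const int ls = (int)s.size();
  for (int fi = from; fi < to; ++fi) {
    if (bestd <= 1) break;  // distance 0 impossible between distinct UMIs
    const int f = founderRows[fi];
    const std::string& fs = seqs[f];
    const int lf = (int)fs.size();
    int cap = thrFor(kmax, ls + lf);
    if (bestd - 1 < cap) cap = bestd - 1;
    if (std::abs(ls - lf) > cap) continue;
    int d;
    if (lf <= 64) {
      d = levMyers(founderMasks[fi], s);
    } else {
      d = levBanded(s, fs, cap);
    }
    if (d <= cap) {
      best = f;
      bestd = d;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cppLevDistance(CharacterVector a, CharacterVector b,
                             IntegerVector cap) {
  const R_xlen_t n = a.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string sa = as<std::string>(a[i]);
    const std::string sb = as<std::string>(b[i]);
    out[i] = levCapped(sa, sb, cap[i]);
  }
  return out;
}

// Greedy founder assignment over UMIs already in processing order
// (read count descending, sequence ascending). Returns, for each UMI, the
// 1-based row of its founder (its own row if it founded a cluster).
//
// Batched producer/consumer layout: for each batch, candidate founders among
// the already-committed list are computed first (split across `workers`
// threads; pure C++, no R API), then a single sequential commit pass makes the
// final decision in sort order, additionally scanning founders created earlier
// within the same batch. Output is identical for every (batchSize, workers).
// [[Rcpp::export]]
IntegerVector cppAssignFounders(CharacterVector umis, IntegerVector kmaxByLen,
                                int batchSize, int workers) {
  const int n = (int)umis.size();
  IntegerVector out(n);
  if (n == 0) return out;
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(umis[i]);
  const std::vector<int> kmax(kmaxByLen.begin(), kmaxByLen.end());
  if (batchSize < 1) batchSize = 1;
  if (workers < 1) workers = 1;

  std::vector<int> founderRows;
  std::vector<PatternMasks> founderMasks;
  founderRows.reserve(4096);
  founderMasks.reserve(4096);
  for (int b0 = 0; b0 < n; b0 += batchSize) {
    const int b1 = std::min(n, b0 + batchSize);
    const int m = b1 - b0;
    const int nOld = (int)founderRows.size();
    std::vector<int> preBest(m, -1);
    std::vector<int> preDist(m, INT_MAX);
    auto consume = [&](int lo, int hi) {
      for (int i = lo; i < hi; ++i) {
        int best = -1, bestd = INT_MAX;
        scanFounders(seqs[b0 + i], seqs, founderRows, founderMasks, 0, nOld,
                     kmax, best, bestd);
        preBest[i] = best;
        preDist[i] = bestd;
      }
    };
    if (workers == 1 || m < 2 || nOld == 0) {
      consume(0, m);
    } else {
      const int nw = std::min(workers, m);
      std::vector<std::thread> pool;
      pool.reserve(nw);
      const int chunk = (m + nw - 1) / nw;
      for (int w = 0; w < nw; ++w) {
        const int lo = w * chunk, hi = std::min(m, lo + chunk);
        if (lo >= hi) break;
        pool.emplace_back(consume, lo, hi);
      }
      for (auto& t : pool) t.join();
    }
    // producer commit pass: strictly in sort order
    for (int i = b0; i < b1; ++i) {
      int best = preBest[i - b0], bestd = preDist[i - b0];
      scanFounders(seqs[i], seqs, founderRows, founderMasks, nOld,
                   (int)founderRows.size(), kmax, best, bestd);
      if (best < 0) {
        founderRows.push_back(i);
        founderMasks.push_back(buildMasks(seqs[i]));
        out[i] = i + 1;
      } else {
        out[i] = best + 1;
      }
    }
  }
  return out;
}

// Pairwise check that every pair of founder sequences is separated by more
// than its pair threshold; returns the number of violating pairs.
// [[Rcpp::export]]
int cppCountFounderViolations(CharacterVector founders,
                              IntegerVector kmaxByLen) {
  const int n = (int)founders.size();
  std::vector<std::string> seqs(n);
  for (int i = 0; i < n; ++i) seqs[i] = as<std::string>(founders[i]);
  const std::vector<int> kmax(kmaxByLen.begin(), kmaxByLen.end());
  int bad = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const int t = thrFor(kmax, (int)seqs[i].size() + (int)seqs[j].size());
      if (std::abs((int)seqs[i].size() - (int)seqs[j].size()) > t) continue;
      if (levCapped(seqs[i], seqs[j], t) <= t) ++bad;
    }
  }
  return bad;
}
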