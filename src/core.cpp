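#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

namespace {

// Suffix array by prefix doubling; O(n log^2 n), adequate for the
// desk-scale inputs this engine targets.  0-based positions internally.
std::vector<int> sa_doubling(const std::vector<int>& s) {
  const int n = static_cast<int>(s.size());
  std::vector<int> sa(n), rk(s.begin(), s.end()), tmp(n);
  std::iota(sa.begin(), sa.end(), 0);
  if (n == 1) return sa;
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rk[a] != rk[b]) return rk[a] < rk[b];
      const int ra = a + k < n ? rk[a + k] : -1;
      const int rb = b + k < n ? rk[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rk.swap(tmp);
    if (rk[sa[n - 1]] == n - 1) break;
  }
  return sa;
}

// Kasai's algorithm: lcp[r] = longest common prefix of suffixes at
// ranks r-1 and r (lcp[0] = 0).
std::vector<int> lcp_kasai(const std::vector<int>& s, const std::vector<int>& sa) {
  const int n = static_cast<int>(s.size());
  std::vector<int> rank_(n), lcp(n, 0);
  for (int r = 0; r < n; ++r) rank_[sa[r]] = r;
  int h = 0;
  for (int i = 0; i < n; ++i) {
    if (rank_[i] > 0) {
      const int j = sa[rank_[i] - 1];
      while (i + h < n && j + h < n && s[i + h] == s[j + h]) ++h;
      lcp[rank_[i]] = h;
      if (h > 0) --h;
    } else {
      h = 0;
    }
  }
  return lcp;
}

struct SparseMin {
  int n = 0;
  std::vector<int> lg;
  std::vector<std::vector<int>> t;
  void build(const std::vector<int>& a) {
    n = static_cast<int>(a.size());
    lg.assign(n + 1, 0);
    for (int i = 2; i <= n; ++i) lg[i] = lg[i / 2] + 1;
    const int K = lg[n] + 1;
    t.assign(K, std::vector<int>());
    t[0] = a;
    for (int k = 1; k < K; ++k) {
      t[k].assign(n, 0);
      for (int i = 0; i + (1 << k) <= n; ++i)
        t[k][i] = std::min(t[k - 1][i], t[k - 1][i + (1 << (k - 1))]);
    }
  }
  // min over inclusive rank range [l, r]; requires 0 <= l <= r < n
  int query(int l, int r) const {
    const int k = lg[r - l + 1];
    return std::min(t[k][l], t[k][r - (1 << k) + 1]);
  }
};

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_suffix_array(IntegerVector text) {
  std::vector<int> s(text.begin(), text.end());
  std::vector<int> sa = sa_doubling(s);
  IntegerVector out(sa.size());
  for (size_t i = 0; i < sa.size(); ++i) out[i] = sa[i] + 1;
  return out;
}

// LPF/POS over a byte sequence.  lpf[i] is the length of the longest
// factor starting at i that also starts at some h < i (self-overlap
// permitted); pos[i] is the leftmost such h, 0 when lpf[i] = 0.
// Computed from SA + LCP: positions are visited in decreasing text
// order while being deleted from a doubly linked list threaded through
// suffix-array rank order, so the list neighbours of rank(i) are the
// lexicographically nearest suffixes starting strictly before i.  The
// leftmost occurrence is recovered by widening the lcp >= lpf[i]
// interval around rank(i) and taking the range-minimum of SA there.
// [[Rcpp::export]]
List cpp_lpf_pos(IntegerVector text) {
  const int n = text.size();
  std::vector<int> s(text.begin(), text.end());
  std::vector<int> sa = sa_doubling(s);
  std::vector<int> lcp = lcp_kasai(s, sa);
  std::vector<int> rank_(n);
  for (int r = 0; r < n; ++r) rank_[sa[r]] = r;

  SparseMin rmq; rmq.build(lcp);
  SparseMin samin; samin.build(sa);

  std::vector<int> prv(n), nxt(n);
  for (int r = 0; r < n; ++r) { prv[r] = r - 1; nxt[r] = r + 1; }

  IntegerVector lpf(n), pos(n);
  for (int i = n - 1; i >= 0; --i) {
    const int r = rank_[i];
    const int pl = prv[r], nx = nxt[r];
    int best = 0;
    if (pl >= 0) best = std::max(best, rmq.query(pl + 1, r));
    if (nx <= n - 1) best = std::max(best, rmq.query(r + 1, nx));
    if (best > 0) {
      int lo = r, hi = r;
      {  // smallest lo with min lcp(lo+1 .. r) >= best
        int a = 0, b = r;
        while (a < b) {
          const int mid = (a + b) / 2;
          if (rmq.query(mid + 1, r) >= best) b = mid; else a = mid + 1;
        }
        lo = a;
      }
      {  // largest hi with min lcp(r+1 .. hi) >= best
        int a = r, b = n - 1;
        while (a < b) {
          const int mid = (a + b + 1) / 2;
          if (rmq.query(r + 1, mid) >= best) a = mid; else b = mid - 1;
        }
        hi = a;
      }
      lpf[i] = best;
      pos[i] = samin.query(lo, hi) + 1;  // 1-based leftmost start
    } else {
      lpf[i] = 0;
      pos[i] = 0;
    }
    if (pl >= 0) nxt[pl] = nx;
    if (nx <= n - 1) prv[nx] = pl;
  }
  return List::create(_["lpf"] = lpf, _["pos"] = pos);
}

// Left-to-right factorization scan of the target region of Z = R.T:
// positions with lpf < k are literals, others become (pT, pZ, l)
// triples and the scan jumps past the factor.
// [[Rcpp::export]]
List cpp_factorize(IntegerVector lpf, IntegerVector pos, int ref_len, int k) {
  const int n = lpf.size();
  std::vector<int> tp, tz, tl, lit;
  int i = ref_len;  // 0-based index of the first target symbol in Z
  while (i < n) {
    if (lpf[i] < k) {
      lit.push_back(i - ref_len + 1);
      ++i;
    } else {
      tp.push_back(i - ref_len + 1);
      tz.push_back(pos[i]);
      tl.push_back(lpf[i]);
      i += lpf[i];
    }
  }
  const int m = static_cast<int>(tp.size());
  IntegerMatrix triples(m, 3);
  for (int t = 0; t < m; ++t) {
    triples(t, 0) = tp[t];
    triples(t, 1) = tz[t];
    triples(t, 2) = tl[t];
  }
  return List::create(_["triples"] = triples, _["literals"] = wrap(lit));
}
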