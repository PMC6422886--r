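#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment under unit edit cost, minimizing
// (cost, paid gap columns, free end columns) lexicographically.
// Packing the three counters into one int64 makes the DP a single min();
// each field gets 21 bits, so sequences up to ~2e6 bases are safe.
static const int FIELD = 21;
static const int64_t ONE_COST = (int64_t)1 << (2 * FIELD);
static const int64_t ONE_GAP  = ((int64_t)1 << (2 * FIELD)) | ((int64_t)1 << FIELD);
static const int64_t ONE_FREE = 1;
static const int64_t INF64 = INT64_MAX / 4;

static inline int64_t sub_cost(char a, char b) {
  // N never matches anything, including another N
  return (a == b && a != 'N') ? 0 : ONE_COST;
}

// Full-matrix DP. end_free allows zero-cost leading/trailing gaps
// (semi-global); free columns are tracked so the aligned core length
// can be recovered without a traceback.
static int64_t align_full(const std::string &a, const std::string &b,
                          bool end_free) {
  const int la = (int)a.size(), lb = (int)b.size();
  std::vector<int64_t> prev(lb + 1), cur(lb + 1);
  std::vector<int64_t> lastcol(la + 1);
  for (int j = 0; j <= lb; ++j)
    prev[j] = end_free ? (int64_t)j * ONE_FREE : (int64_t)j * ONE_GAP;
  lastcol[0] = prev[lb];
  for (int i = 1; i <= la; ++i) {
    cur[0] = end_free ? (int64_t)i * ONE_FREE : (int64_t)i * ONE_GAP;
    for (int j = 1; j <= lb; ++j) {
      int64_t v = prev[j - 1] + sub_cost(a[i - 1], b[j - 1]);
      int64_t v2 = prev[j] + ONE_GAP;
      int64_t v3 = cur[j - 1] + ONE_GAP;
      if (v2 < v) v = v2;
      if (v3 < v) v = v3;
      cur[j] = v;
    }
    std::swap(prev, cur);
    lastcol[i] = prev[lb];
  }
  if (!end_free) return prev[lb];
  // free trailing gaps: finish from any cell on the last row or column
  int64_t best = INF64;
  for (int j = 0; j <= lb; ++j) {
    int64_t v = prev[j] + (int64_t)(lb - j) * ONE_FREE;
    if (v < best) best = v;
  }
  for (int i = 0; i <= la; ++i) {
    int64_t v = lastcol[i] + (int64_t)(la - i) * ONE_FREE;
    if (v < best) best = v;
  }
  return best;
}

// Banded DP over diagonals j - i in [min(0,lb-la)-w, max(0,lb-la)+w].
// If the returned cost is <= w the result equals the full DP (any
// optimal path with cost <= w stays inside the band); otherwise the
// value is only an upper bound on the true cost.
static int64_t align_banded(const std::string &a, const std::string &b,
                            int w) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int lo = std::min(0, lb - la) - w;
  const int hi = std::max(0, lb - la) + w;
  const int width = hi - lo + 1;
  std::vector<int64_t> prev(width, INF64), cur(width, INF64);
  for (int j = std::max(0, lo); j <= std::min(lb, hi); ++j)
    prev[j - lo] = (int64_t)j * ONE_GAP;
  for (int i = 1; i <= la; ++i) {
    const int jmin = std::max(0, i + lo), jmax = std::min(lb, i + hi);
    std::fill(cur.begin(), cur.end(), INF64);
    for (int j = jmin; j <= jmax; ++j) {
      const int idx = j - i - lo;
      int64_t v = INF64;
      if (j >= 1 && prev[idx] < INF64)
        v = prev[idx] + sub_cost(a[i - 1], b[j - 1]);
      if (idx + 1 < width && prev[idx + 1] < INF64) {
        int64_t v2 = prev[idx + 1] + ONE_GAP;
        if (v2 < v) v = v2;
      }
      if (idx - 1 >= 0 && j >= 1 && cur[idx - 1] < INF64) {
        int64_t v3 = cur[idx - 1] + ONE_GAP;
        if (v3 < v) v = v3;
      }
      cur[idx] = v;
    }
    std::swap(prev, cur);
  }
  return prev[lb - la - lo];
}

// Exact alignment by adaptive band doubling; always returns the full-DP
// optimum (the band is widened until the optimum is provably inside it).
static int64_t align_exact(const std::string &a, const std::string &b) {
  const int la = (int)a.size(), lb = (int)b.size();
  const int minlen = std::min(la, lb);
  int w = 8;
  for (;;) {
    int64_t v = align_banded(a, b, w);
    int64_t cost = v >> (2 * FIELD);
    if (cost <= w || w >= minlen) return v;
    w = std::min(minlen, 2 * w);
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_dist_batch(std::string query, CharacterVector targets,
                             double cutoff, bool end_free, int normalize,
                             bool gap_diff, bool full) {
  const int n = targets.size();
  NumericMatrix out(n, 3);
  colnames(out) = CharacterVector::create("d", "rawD", "L");
  const int la = (int)query.size();
  if (la == 0) stop("empty query sequence");
  for (int t = 0; t < n; ++t) {
    std::string b = as<std::string>(targets[t]);
    const int lb = (int)b.size();
    if (lb == 0) stop("empty target sequence");
    int64_t v;
    bool exact = true;
    if (end_free || full) {
      v = align_full(query, b, end_free);
    } else if (cutoff < 0) {
      v = align_exact(query, b);
    } else {
      int w = (int)std::ceil(cutoff * (la + lb)) + 1;
      if (w >= std::min(la, lb)) {
        v = align_full(query, b, false);
      } else {
        v = align_banded(query, b, w);
        int64_t cost = v >> (2 * FIELD);
        exact = cost <= w;
      }
    }
    if (!exact) {
      out(t, 0) = R_PosInf;
      out(t, 1) = NA_REAL;
      out(t, 2) = NA_REAL;
      continue;
    }
    const int64_t cost = v >> (2 * FIELD);
    const int64_t gaps = (v >> FIELD) & (((int64_t)1 << FIELD) - 1);
    const int64_t freec = v & (((int64_t)1 << FIELD) - 1);
    const double num = gap_diff ? (double)cost : (double)(cost - gaps);
    double L;
    if (normalize == 1) {
      L = (double)std::min(la, lb);
    } else {
      L = ((double)(la + lb - freec) + (double)gaps) / 2.0;
    }
    double d = L > 0 ? num / L : 0.0;
    if (d > 1.0) d = 1.0;
    out(t, 0) = d;
    out(t, 1) = (double)cost;
    out(t, 2) = L;
  }
  return out;
}
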