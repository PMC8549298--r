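#include "core.h"

namespace hb {

// piecewise-linear band centre through the anchor chain
static void build_band(const std::vector<Anchor>& anchors, int n, int m,
                       bool pin_ends, int hw,
                       std::vector<int>& lo, std::vector<int>& hi) {
  std::vector<Anchor> pts;
  if (pin_ends) pts.push_back({0, 0});
  int pq = -1, pt = -1;
  for (const auto& a : anchors) {
    if (a.q < 0 || a.q > n || a.t < 0 || a.t > m) continue;
    if (a.q <= pq || a.t <= pt) continue;  // keep strictly increasing
    pts.push_back(a);
    pq = a.q; pt = a.t;
  }
  if (pin_ends) pts.push_back({n, m});
  lo.assign(n + 1, 0);
  hi.assign(n + 1, m);
  auto center_at = [&](int i) -> double {
    if (pts.empty()) return (double)i * ((double)m / std::max(1, n));
    if (i <= pts.front().q) return pts.front().t - (double)(pts.front().q - i);
    if (i >= pts.back().q) return pts.back().t + (double)(i - pts.back().q);
    // binary search for segment
    int loi = 0, hii = (int)pts.size() - 1;
    while (loi + 1 < hii) {
      int mid = (loi + hii) / 2;
      if (pts[mid].q <= i) loi = mid; else hii = mid;
    }
    const Anchor& a = pts[loi];
    const Anchor& b = pts[hii];
    double f = (double)(i - a.q) / std::max(1, b.q - a.q);
    return a.t + f * (b.t - a.t);
  };
  for (int i = 0; i <= n; ++i) {
    double c = center_at(i);
    int l = (int)(c - hw), h = (int)(c + hw);
    lo[i] = std::min(std::max(l, 0), m);
    hi[i] = std::max(std::min(h, m), 0);
  }
  // enforce monotone, non-empty, connected windows
  for (int i = 1; i <= n; ++i) {
    if (lo[i] < lo[i - 1]) lo[i] = lo[i - 1];
    if (hi[i] < hi[i - 1]) hi[i] = hi[i - 1];
    if (lo[i] > hi[i]) lo[i] = hi[i];
  }
}

int banded_edit(const std::string& A, int as, int ae,
                const std::string& B, int bs, int be,
                const std::vector<Anchor>& anchors, int hw) {
  const int n = ae - as, m = be - bs;
  if (n <= 0) return m;
  if (m <= 0) return n;
  std::vector<int> lo, hi;
  build_band(anchors, n, m, true, hw, lo, hi);

  std::vector<int> prev(hi[0] - lo[0] + 1), cur;
  for (int j = lo[0]; j <= hi[0]; ++j) prev[j - lo[0]] = j;
  for (int i = 1; i <= n; ++i) {
    cur.assign(hi[i] - lo[i] + 1, ALN_INF);
    const char ac = A[as + i - 1];
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int best = ALN_INF;
      if (j == 0) {
        best = i;
      } else {
        if (j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
          int v = prev[j - 1 - lo[i - 1]] + (ac != B[bs + j - 1]);
          if (v < best) best = v;
        }
        if (j - 1 >= lo[i]) {
          int v = cur[j - 1 - lo[i]];
          if (v < ALN_INF) { v += 1; if (v < best) best = v; }
        }
        if (j >= lo[i - 1] && j <= hi[i - 1]) {
          int v = prev[j - lo[i - 1]] + 1;
          if (v < best) best = v;
        }
      }
      cur[j - lo[i]] = best;
    }
    std::swap(prev, cur);
  }
  if (m >= lo[n] && m <= hi[n]) {
    int v = prev[m - lo[n]];
    return v;
  }
  return ALN_INF;
}

AlnResult fit_align(const std::string& q, const std::string& qual,
                    const std::string& ref, int ts, int te,
                    const std::vector<Anchor>& anchors, int hw) {
  AlnResult res;
  const int n = (int)q.size();
  const int m = te - ts;
  if (n == 0 || m <= 0) return res;
  std::vector<int> lo, hi;
  build_band(anchors, n, m, false, hw, lo, hi);

  // backpointers: 0 start, 1 diag, 2 up (query ins), 3 left (query del)
  std::vector<int> rowoff(n + 1);
  size_t tot = 0;
  for (int i = 0; i <= n; ++i) { rowoff[i] = (int)tot; tot += hi[i] - lo[i] + 1; }
  std::vector<uint8_t> bp(tot, 0);

  std::vector<int> prev(hi[0] - lo[0] + 1, 0), cur;  // free leading ref gap
  for (int i = 1; i <= n; ++i) {
    cur.assign(hi[i] - lo[i] + 1, ALN_INF);
    const char ac = q[i - 1];
    uint8_t* bprow = &bp[rowoff[i]];
    for (int j = lo[i]; j <= hi[i]; ++j) {
      int best = ALN_INF; uint8_t ptr = 0;
      if (j - 1 >= lo[i - 1] && j - 1 <= hi[i - 1]) {
        int v = prev[j - 1 - lo[i - 1]];
        if (v < ALN_INF) { v += (ac != ref[ts + j - 1]); if (v < best) { best = v; ptr = 1; } }
      }
      if (j >= lo[i - 1] && j <= hi[i - 1]) {
        int v = prev[j - lo[i - 1]];
        if (v < ALN_INF) { v += 1; if (v < best) { best = v; ptr = 2; } }
      }
      if (j - 1 >= lo[i]) {
        int v = cur[j - 1 - lo[i]];
        if (v < ALN_INF) { v += 1; if (v < best) { best = v; ptr = 3; } }
      }
      cur[j - lo[i]] = best;
      bprow[j - lo[i]] = ptr;
    }
    std::swap(prev, cur);
  }

  // free trailing ref gap: best cell in the last row
  int jend = -1, bestv = ALN_INF;
  for (int j = lo[n]; j <= hi[n]; ++j) {
    int v = prev[j - lo[n]];
    if (v < bestv) { bestv = v; jend = j; }
  }
  if (jend < 0 || bestv >= ALN_INF) return res;

  // traceback
  std::vector<uint8_t> ops;  // in reverse order
  int i = n, j = jend;
  while (i > 0) {
    uint8_t p = bp[rowoff[i] + (j - lo[i])];
    if (p == 0) break;  // start cell within row 0 only
    ops.push_back(p);
    if (p == 1) { --i; --j; }
    else if (p == 2) { --i; }
    else { --j; }
  }
  if (i > 0) return res;  // band degenerated
  int jstart = j;
  std::reverse(ops.begin(), ops.end());

  // strip unaligned query flanks (leading/trailing insertion runs)
  size_t b = 0, e = ops.size();
  int qs = 0, qe = n;
  while (b < e && ops[b] == 2) { ++b; ++qs; }
  while (e > b && ops[e - 1] == 2) { --e; --qe; }
  if (b == e) return res;

  const bool has_qual = qual.size() == q.size();
  std::string row, qrow, pending;
  std::vector<std::pair<int, std::string>> ins;
  int qi = qs, rj = jstart, dist = 0;
  for (size_t oi = b; oi < e; ++oi) {
    uint8_t p = ops[oi];
    if (p == 1) {
      if (!pending.empty()) { ins.emplace_back(ts + rj, pending); pending.clear(); }
      char qc = q[qi];
      row.push_back(qc);
      qrow.push_back(has_qual ? qual[qi] : 'I');
      if (qc != ref[ts + rj]) ++dist;
      ++qi; ++rj;
    } else if (p == 2) {
      pending.push_back(q[qi]);
      ++qi; ++dist;
    } else {
      if (!pending.empty()) { ins.emplace_back(ts + rj, pending); pending.clear(); }
      row.push_back('-');
      qrow.push_back('+');
      ++rj; ++dist;
    }
  }
  res.ok = true;
  res.ref_start = ts + jstart;
  res.ref_end = ts + rj;
  res.q_start = qs;
  res.q_end = qe;
  res.dist = dist;
  res.row = std::move(row);
  res.qrow = std::move(qrow);
  res.ins = std::move(ins);
  return res;
}

}  // namespace hb
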