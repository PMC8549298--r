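#include "core.h"
#include <deque>

namespace hb {

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = compl_base(s[i]);
  return r;
}

static inline int base2bit(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
  }
  return -1;
}

// invertible 64-bit integer finaliser; decorrelates k-mer rank from sequence
static inline uint64_t hash64(uint64_t key, uint64_t mask) {
  key = (~key + (key << 21)) & mask;
  key = key ^ (key >> 24);
  key = ((key + (key << 3)) + (key << 8)) & mask;
  key = key ^ (key >> 14);
  key = ((key + (key << 2)) + (key << 4)) & mask;
  key = key ^ (key >> 28);
  key = (key + (key << 31)) & mask;
  return key;
}

std::vector<Mini> sketch(const std::string& s, int k, int w) {
  std::vector<Mini> out;
  const int n = (int)s.size();
  if (n < k) return out;
  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  const uint64_t shift = 2 * (k - 1);

  // per-position canonical k-mer hashes; UINT64_MAX marks invalid (non-ACGT)
  std::vector<uint64_t> hv(n - k + 1, UINT64_MAX);
  std::vector<uint8_t> sv(n - k + 1, 0);
  uint64_t f = 0, r = 0;
  int l = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { l = 0; f = r = 0; continue; }
    f = ((f << 2) | (uint64_t)b) & mask;
    r = (r >> 2) | (((uint64_t)(3 - b)) << shift);
    if (++l >= k) {
      int pos = i - k + 1;
      if (f == r) continue;  // palindromic k-mer: strand ambiguous, skip
      uint64_t canon = std::min(f, r);
      hv[pos] = hash64(canon, mask);
      sv[pos] = (r < f);
    }
  }

  // sliding-window minimum over w consecutive k-mer starts
  std::deque<int> dq;
  const int np = n - k + 1;
  int lastpos = -1;
  for (int i = 0; i < np; ++i) {
    if (hv[i] != UINT64_MAX) {
      while (!dq.empty() && hv[dq.back()] >= hv[i]) dq.pop_back();
      dq.push_back(i);
    }
    while (!dq.empty() && dq.front() <= i - w) dq.pop_front();
    if (i >= w - 1 && !dq.empty()) {
      int p = dq.front();
      if (p != lastpos) {
        out.push_back({hv[p], p, sv[p]});
        lastpos = p;
      }
    }
  }
  // very short sequences (< k + w - 1): emit the global minimum
  if (out.empty() && np > 0) {
    int best = -1;
    for (int i = 0; i < np; ++i)
      if (hv[i] != UINT64_MAX && (best < 0 || hv[i] < hv[best])) best = i;
    if (best >= 0) out.push_back({hv[best], best, sv[best]});
  }
  return out;
}

// LIS-based chaining: sort by (q asc, t desc), then longest strictly increasing
// subsequence on t gives a chain strictly increasing in both coordinates.
std::vector<Anchor> chain_anchors(std::vector<Anchor>& a) {
  std::vector<Anchor> chain;
  if (a.empty()) return chain;
  std::sort(a.begin(), a.end(), [](const Anchor& x, const Anchor& y) {
    if (x.q != y.q) return x.q < y.q;
    return x.t > y.t;
  });
  const int n = (int)a.size();
  std::vector<int> tails;      // indices into a; a[tails[len]].t minimal tail
  std::vector<int> parent(n, -1);
  for (int i = 0; i < n; ++i) {
    int lo = 0, hi = (int)tails.size();
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (a[tails[mid]].t < a[i].t) lo = mid + 1; else hi = mid;
    }
    if (lo > 0) parent[i] = tails[lo - 1];
    if (lo == (int)tails.size()) tails.push_back(i);
    else tails[lo] = i;
  }
  int cur = tails.back();
  while (cur >= 0) { chain.push_back(a[cur]); cur = parent[cur]; }
  std::reverse(chain.begin(), chain.end());
  return chain;
}

int guide_halfwidth(const std::vector<Anchor>& anchors,
                    int qs, int qe, int ts, int te,
                    double band_frac, int min_hw) {
  int maxgap = 0;
  int pq = qs, pt = ts;
  for (const auto& an : anchors) {
    maxgap = std::max(maxgap, std::max(an.q - pq, an.t - pt));
    pq = an.q; pt = an.t;
  }
  maxgap = std::max(maxgap, std::max(qe - pq, te - pt));
  int hw = (int)(band_frac * maxgap) + 8;
  return std::max(hw, min_hw);
}

}  // namespace hb
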