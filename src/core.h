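#pragma once

#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <utility>

namespace hb {

constexpr int ALN_INF = 1 << 28;

inline char compl_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
  }
  return 'N';
}

std::string revcomp(const std::string& s);

struct Mini {
  uint64_t h;
  int pos;       // 0-based start of the k-mer
  int strand;    // 0 if the forward k-mer is canonical, 1 if the reverse complement is
};

std::vector<Mini> sketch(const std::string& s, int k, int w);

struct Anchor { int q, t; };

// maximal colinear chain (strictly increasing in both coordinates)
std::vector<Anchor> chain_anchors(std::vector<Anchor>& a);

// half band width that tracks the largest gap between consecutive chain anchors
int guide_halfwidth(const std::vector<Anchor>& anchors,
                    int qs, int qe, int ts, int te,
                    double band_frac, int min_hw);

// banded global edit distance of A[as,ae) vs B[bs,be); band centre follows the
// piecewise-linear diagonal through `anchors` (given in *local* coordinates of
// the two spans). Returns ALN_INF if the optimum leaves the band.
int banded_edit(const std::string& A, int as, int ae,
                const std::string& B, int bs, int be,
                const std::vector<Anchor>& anchors, int hw);

struct AlnResult {
  bool ok = false;
  int ref_start = 0, ref_end = 0;  // aligned reference span (absolute coords)
  int q_start = 0, q_end = 0;      // aligned span on the (oriented) query
  int dist = 0;                    // edit distance of the aligned region
  std::string row;                 // query base per reference position; '-' = deletion
  std::string qrow;                // quality char per reference position ('!' fill)
  std::vector<std::pair<int, std::string>> ins;  // insertions keyed by ref position
};

// fitting alignment: the query is aligned end-to-end (minus unalignable flanks),
// the reference is free to start/end anywhere inside [ts, te).
AlnResult fit_align(const std::string& q, const std::string& qual,
                    const std::string& ref, int ts, int te,
                    const std::vector<Anchor>& anchors, int hw);

}  // namespace hb
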