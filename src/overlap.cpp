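#include <Rcpp.h>
#include "core.h"
#include <unordered_map>

using namespace Rcpp;

namespace {

struct Hit { int rid, pos; uint8_t strand; };

}  // namespace

// All-vs-all overlap candidates among `seqs` (assumed sorted by id upstream so
// that index order == canonical pair order). For each unordered pair and
// orientation at most one overlap is emitted, with the smaller index as query.
// Coordinates are end-extended when the chain overhang is at most max_hang_ext,
// so proper dovetails/containments reach the read ends; identity comes from a
// chain-guided banded edit distance over the (extended) span.
// [[Rcpp::export]]
DataFrame cpp_find_overlaps(CharacterVector seqs, int k, int w,
                            int min_shared, int max_occ,
                            double band_frac, int min_hw,
                            int min_span, int max_hang_ext) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n), rc(n);
  for (int i = 0; i < n; ++i) fwd[i] = as<std::string>(seqs[i]);

  std::unordered_map<uint64_t, std::vector<Hit>> index;
  index.reserve(1 << 16);

  std::vector<int> out_qi, out_ti, out_qs, out_qe, out_ts, out_te;
  std::vector<int> out_nm, out_bl;
  std::vector<std::string> out_strand;

  for (int i = 0; i < n; ++i) {
    std::vector<hb::Mini> mins = hb::sketch(fwd[i], k, w);
    const int qlen = (int)fwd[i].size();

    // collect anchors against already-indexed reads, keyed by (read, relative strand)
    std::unordered_map<int64_t, std::vector<hb::Anchor>> cand;
    for (const auto& mn : mins) {
      auto it = index.find(mn.h);
      if (it == index.end()) continue;
      if ((int)it->second.size() > max_occ) continue;
      for (const auto& ht : it->second) {
        int rel = (mn.strand != ht.strand) ? 1 : 0;
        int tlen = (int)fwd[ht.rid].size();
        int tpos = rel ? (tlen - ht.pos - k) : ht.pos;
        cand[((int64_t)ht.rid << 1) | rel].push_back({mn.pos, tpos});
      }
    }

    for (auto& kv : cand) {
      if ((int)kv.second.size() < min_shared) continue;
      const int j = (int)(kv.first >> 1);
      const int rel = (int)(kv.first & 1);
      std::vector<hb::Anchor> chain = hb::chain_anchors(kv.second);
      if ((int)chain.size() < min_shared) continue;
      const int tlen = (int)fwd[j].size();
      int qs = chain.front().q, qe = chain.back().q + k;
      int ts = chain.front().t, te = chain.back().t + k;
      if (std::max(qe - qs, te - ts) < min_span) continue;

      int oh = std::min(qs, ts) + std::min(qlen - qe, tlen - te);
      if (oh <= max_hang_ext) {
        int dl = std::min(qs, ts);
        qs -= dl; ts -= dl;
        int dr = std::min(qlen - qe, tlen - te);
        qe += dr; te += dr;
      }

      if (rel && rc[j].empty()) rc[j] = hb::revcomp(fwd[j]);
      const std::string& T = rel ? rc[j] : fwd[j];

      std::vector<hb::Anchor> local;
      local.reserve(chain.size());
      for (const auto& a : chain) local.push_back({a.q - qs, a.t - ts});
      int hw = hb::guide_halfwidth(local, 0, qe - qs, 0, te - ts, band_frac, min_hw);
      int d = hb::banded_edit(fwd[i], qs, qe, T, ts, te, local, hw);
      if (d >= hb::ALN_INF) d = hb::banded_edit(fwd[i], qs, qe, T, ts, te, local, 4 * hw);
      if (d >= hb::ALN_INF) continue;

      int blocklen = std::max(qe - qs, te - ts);
      int nmatch = std::max(0, blocklen - d);
      // target coords back to its forward strand
      int Ts = rel ? (tlen - te) : ts;
      int Te = rel ? (tlen - ts) : te;
      // emit with the earlier (smaller-id) read j as query
      out_qi.push_back(j + 1);
      out_qs.push_back(Ts);
      out_qe.push_back(Te);
      out_ti.push_back(i + 1);
      out_ts.push_back(qs);
      out_te.push_back(qe);
      out_strand.push_back(rel ? "-" : "+");
      out_nm.push_back(nmatch);
      out_bl.push_back(blocklen);
    }

    for (const auto& mn : mins) {
      auto& v = index[mn.h];
      if ((int)v.size() <= max_occ) v.push_back({i, mn.pos, (uint8_t)mn.strand});
    }
  }

  return DataFrame::create(
      _["qi"] = out_qi, _["qs"] = out_qs, _["qe"] = out_qe,
      _["ti"] = out_ti, _["ts"] = out_ts, _["te"] = out_te,
      _["strand"] = out_strand, _["nmatch"] = out_nm, _["blocklen"] = out_bl,
      _["stringsAsFactors"] = false);
}
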