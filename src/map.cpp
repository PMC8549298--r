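#include <Rcpp.h>
#include "core.h"
#include <unordered_map>
#include <map>

using namespace Rcpp;

// Map each read to a single reference sequence (both strands tried; the strand
// with the longer anchor chain wins) and report a base-level fitting alignment:
// per-reference-position read bases ("row" strings, '-' for deletions) plus
// insertion records. Used for polishing, SNP calling, correction and evaluation.
// [[Rcpp::export]]
List cpp_map_reads(std::string ref, CharacterVector reads, CharacterVector quals,
                   int k, int w, int min_shared, int max_occ,
                   double band_frac, int min_hw, int pad) {
  const int nr = reads.size();
  const int reflen = (int)ref.size();
  std::vector<hb::Mini> rmins = hb::sketch(ref, k, w);
  std::unordered_map<uint64_t, std::vector<std::pair<int, uint8_t>>> index;
  index.reserve(rmins.size() * 2);
  for (const auto& mn : rmins) index[mn.h].push_back({mn.pos, (uint8_t)mn.strand});

  LogicalVector ok(nr);
  CharacterVector strand(nr), rows(nr), qrows(nr);
  IntegerVector ref_start(nr), ref_end(nr), q_start(nr), q_end(nr), dist(nr);
  std::vector<int> ins_read, ins_pos;
  std::vector<std::string> ins_seq;

  const bool have_quals = quals.size() == nr;

  for (int r = 0; r < nr; ++r) {
    ok[r] = false;
    strand[r] = NA_STRING; rows[r] = NA_STRING; qrows[r] = NA_STRING;
    ref_start[r] = NA_INTEGER; ref_end[r] = NA_INTEGER;
    q_start[r] = NA_INTEGER; q_end[r] = NA_INTEGER; dist[r] = NA_INTEGER;

    std::string q = as<std::string>(reads[r]);
    const int qlen = (int)q.size();
    if (qlen < k) continue;
    std::vector<hb::Mini> qmins = hb::sketch(q, k, w);
    std::vector<hb::Anchor> fwd_a, rev_a;  // anchors on fwd / revcomp of the read
    for (const auto& mn : qmins) {
      auto it = index.find(mn.h);
      if (it == index.end() || (int)it->second.size() > max_occ) continue;
      for (const auto& ht : it->second) {
        if (ht.second == mn.strand) fwd_a.push_back({mn.pos, ht.first});
        else rev_a.push_back({qlen - mn.pos - k, ht.first});
      }
    }
    std::vector<hb::Anchor> cf = hb::chain_anchors(fwd_a);
    std::vector<hb::Anchor> cr = hb::chain_anchors(rev_a);
    bool use_rev = cr.size() > cf.size();
    std::vector<hb::Anchor>& chain = use_rev ? cr : cf;
    if ((int)chain.size() < min_shared) continue;

    std::string oq = use_rev ? hb::revcomp(q) : q;
    std::string oqual;
    if (have_quals && quals[r] != NA_STRING) {
      oqual = as<std::string>(quals[r]);
      if (use_rev) std::reverse(oqual.begin(), oqual.end());
    }

    int q0 = chain.front().q, t0 = chain.front().t;
    int q1 = chain.back().q + k, t1 = chain.back().t + k;
    int ts0 = std::max(0, t0 - q0 - pad);
    int te0 = std::min(reflen, t1 + (qlen - q1) + pad);
    std::vector<hb::Anchor> local;
    local.reserve(chain.size());
    for (const auto& a : chain) local.push_back({a.q, a.t - ts0});
    int hw = hb::guide_halfwidth(local, 0, qlen, 0, te0 - ts0, band_frac, min_hw);
    hb::AlnResult res = hb::fit_align(oq, oqual, ref, ts0, te0, local, hw);
    if (!res.ok) {
      res = hb::fit_align(oq, oqual, ref, ts0, te0, local, 4 * hw);
      if (!res.ok) continue;
    }
    ok[r] = true;
    strand[r] = use_rev ? "-" : "+";
    ref_start[r] = res.ref_start; ref_end[r] = res.ref_end;
    q_start[r] = res.q_start; q_end[r] = res.q_end;
    dist[r] = res.dist;
    rows[r] = res.row;
    qrows[r] = res.qrow;
    for (const auto& pr : res.ins) {
      ins_read.push_back(r + 1);
      ins_pos.push_back(pr.first);
      ins_seq.push_back(pr.second);
    }
  }

  return List::create(
      _["ok"] = ok, _["strand"] = strand,
      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
      _["q_start"] = q_start, _["q_end"] = q_end, _["dist"] = dist,
      _["row"] = rows, _["qrow"] = qrows,
      _["ins"] = DataFrame::create(_["read"] = ins_read, _["pos"] = ins_pos,
                                   _["seq"] = ins_seq,
                                   _["stringsAsFactors"] = false));
}

// Pileup consensus over a reference from "row" strings. Column symbols are
// chosen by (quality-)weighted majority among covering reads, with the
// reference base breaking ties; deletions win a column by majority and drop
// the base; an insertion is applied when one inserted string is carried by
// more than half of the reads covering the junction.
// [[Rcpp::export]]
List cpp_consensus(std::string ref, IntegerVector starts, CharacterVector rows,
                   CharacterVector qrows,
                   IntegerVector ins_read, IntegerVector ins_pos,
                   CharacterVector ins_seq) {
  const int L = (int)ref.size();
  const int nr = rows.size();
  const bool have_q = qrows.size() == nr;

  std::vector<std::array<double, 6>> wts(L, {0, 0, 0, 0, 0, 0});  // A C G T N -
  std::vector<int> cov(L, 0);
  auto sym_idx = [](char c) -> int {
    switch (c) {
      case 'A': return 0; case 'C': return 1; case 'G': return 2;
      case 'T': return 3; case '-': return 5;
    }
    return 4;
  };
  for (int r = 0; r < nr; ++r) {
    if (rows[r] == NA_STRING) continue;
    std::string row = as<std::string>(rows[r]);
    std::string qr = have_q && qrows[r] != NA_STRING ? as<std::string>(qrows[r]) : std::string();
    int s = starts[r];
    for (int i = 0; i < (int)row.size(); ++i) {
      int p = s + i;
      if (p < 0 || p >= L) continue;
      double wt = (qr.size() == row.size()) ? std::max(1, (int)qr[i] - 33) : 1.0;
      wts[p][sym_idx(row[i])] += wt;
      cov[p] += 1;
    }
  }

  // insertion votes per junction (count-based; one vote per covering read)
  std::map<int, std::map<std::string, int>> insvotes;
  for (int t = 0; t < ins_read.size(); ++t) {
    insvotes[ins_pos[t]][as<std::string>(ins_seq[t])] += 1;
  }
  // reads covering each junction with pending insertions
  std::map<int, int> junc_cov;
  for (auto& kv : insvotes) {
    int p = kv.first;
    int c = 0;
    for (int r = 0; r < nr; ++r) {
      if (rows[r] == NA_STRING) continue;
      int s = starts[r];
      int e = s + (int)Rf_length(STRING_ELT(rows, r));
      if (p > s && p < e) ++c;
    }
    junc_cov[p] = c;
  }

  static const char SYM[6] = {'A', 'C', 'G', 'T', 'N', '-'};
  std::string out;
  out.reserve(L + 64);
  std::vector<int> outcov;
  outcov.reserve(L + 64);
  IntegerVector refmap(L + 1);

  for (int p = 0; p < L; ++p) {
    // insertion before column p
    auto iv = insvotes.find(p);
    if (iv != insvotes.end() && p > 0) {
      int total = junc_cov[p];
      const std::string* best = nullptr;
      int bestc = 0, nonempty = 0;
      for (const auto& kv : iv->second) {
        nonempty += kv.second;
        if (kv.second > bestc) { bestc = kv.second; best = &kv.first; }
      }
      // insert when the reads carrying an insertion outnumber those without;
      // the inserted string is the plurality vote (votes may split across
      // error variants of the same true insertion)
      if (best && 2 * nonempty > total) {
        out += *best;
        for (size_t z = 0; z < best->size(); ++z) outcov.push_back(bestc);
      }
    }
    refmap[p] = (int)out.size();
    if (cov[p] == 0) { out.push_back(ref[p]); outcov.push_back(0); continue; }
    int best = 0;
    double bw = -1;
    int refi = sym_idx(ref[p]);
    for (int s6 = 0; s6 < 6; ++s6) {
      double wv = wts[p][s6];
      if (wv > bw || (wv == bw && s6 == refi && best != refi)) { bw = wv; best = s6; }
    }
    if (best == 4) best = refi;  // never emit N from ambiguous votes
    if (best != 5) { out.push_back(SYM[best]); outcov.push_back(cov[p]); }
  }
  refmap[L] = (int)out.size();

  return List::create(_["seq"] = out, _["cov"] = wrap(outcov), _["refmap"] = refmap);
}

// base counts per reference position (rows A, C, G, T, N, del)
// [[Rcpp::export]]
IntegerMatrix cpp_base_counts(int ref_len, IntegerVector starts, CharacterVector rows) {
  IntegerMatrix m(6, ref_len);
  for (int r = 0; r < rows.size(); ++r) {
    if (rows[r] == NA_STRING) continue;
    std::string row = as<std::string>(rows[r]);
    int s = starts[r];
    for (int i = 0; i < (int)row.size(); ++i) {
      int p = s + i;
      if (p < 0 || p >= ref_len) continue;
      int idx;
      switch (row[i]) {
        case 'A': idx = 0; break; case 'C': idx = 1; break;
        case 'G': idx = 2; break; case 'T': idx = 3; break;
        case '-': idx = 5; break; default: idx = 4;
      }
      m(idx, p) += 1;
    }
  }
  rownames(m) = CharacterVector::create("A", "C", "G", "T", "N", "del");
  return m;
}
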