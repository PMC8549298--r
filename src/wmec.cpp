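#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Exact weighted minimum error correction by column-sweep dynamic programming.
//
// Entries are (row, col, allele, weight) triplets of the (already coverage-
// capped) allele matrix. A read is "active" at every column of its span
// (first..last column carrying one of its entries), so the bipartition is a
// single variable per read, as in the exhaustive formulation. States are
// bitmask bipartitions of the active set of a column; transitions force
// agreement on reads shared between consecutive columns. Backtrace uses
// checkpointed forward arrays to keep memory bounded.
//
// Returns the optimal cost and one optimal side (0/1) per row (NA for rows
// with no entries).
// [[Rcpp::export]]
List cpp_wmec(IntegerVector row, IntegerVector col, IntegerVector allele,
              NumericVector weight, int n_rows, int n_cols) {
  const int ne = row.size();
  List out;
  if (n_cols == 0 || ne == 0) {
    IntegerVector side(n_rows, NA_INTEGER);
    return List::create(_["cost"] = 0.0, _["side"] = side);
  }

  // span per row
  std::vector<int> first(n_rows, n_cols), last(n_rows, -1);
  for (int t = 0; t < ne; ++t) {
    int r = row[t], c = col[t];
    first[r] = std::min(first[r], c);
    last[r] = std::max(last[r], c);
  }

  // active rows per column (sorted by row index), and entry lists
  std::vector<std::vector<int>> active(n_cols);
  for (int r = 0; r < n_rows; ++r)
    for (int c = first[r]; c <= last[r]; ++c) active[c].push_back(r);
  for (int c = 0; c < n_cols; ++c) {
    std::sort(active[c].begin(), active[c].end());
    if ((int)active[c].size() > 25)
      stop("wMEC column coverage %d exceeds the hard limit of 25; downsample first",
           (int)active[c].size());
  }
  // entry weights per column, indexed by bit position in the active mask
  std::vector<std::vector<double>> w0(n_cols), w1(n_cols);  // cost contributions
  for (int c = 0; c < n_cols; ++c) {
    w0[c].assign(active[c].size(), 0.0);
    w1[c].assign(active[c].size(), 0.0);
  }
  for (int t = 0; t < ne; ++t) {
    int r = row[t], c = col[t];
    int b = (int)(std::lower_bound(active[c].begin(), active[c].end(), r) -
                  active[c].begin());
    if (allele[t] == 0) w0[c][b] += weight[t];   // flipped if side-allele is 1
    else w1[c][b] += weight[t];                  // flipped if side-allele is 0
  }

  const double FINF = 1.0e300;

  // column cost over all bipartition masks
  auto colcost = [&](int c, std::vector<double>& out_cc) {
    const int nc = (int)active[c].size();
    const uint32_t nstates = 1u << nc;
    const uint32_t full = nstates - 1;
    std::vector<double> cA(nstates), cB(nstates);  // side allele 0 / 1 costs
    cA[0] = cB[0] = 0.0;
    for (uint32_t S = 1; S < nstates; ++S) {
      uint32_t low = S & (~S + 1);
      int b = __builtin_ctz(S);
      cA[S] = cA[S ^ low] + w1[c][b];
      cB[S] = cB[S ^ low] + w0[c][b];
    }
    out_cc.resize(nstates);
    for (uint32_t S = 0; S < nstates; ++S) {
      double s1 = std::min(cA[S], cB[S]);
      uint32_t T = full ^ S;
      double s2 = std::min(cA[T], cB[T]);
      out_cc[S] = s1 + s2;
    }
  };

  // intersection bit maps between consecutive columns
  struct Isect { std::vector<int> prev_bits, cur_bits; };
  std::vector<Isect> isect(n_cols);
  for (int c = 1; c < n_cols; ++c) {
    const auto& A = active[c - 1];
    const auto& B = active[c];
    size_t i = 0, j = 0;
    while (i < A.size() && j < B.size()) {
      if (A[i] < B[j]) ++i;
      else if (A[i] > B[j]) ++j;
      else { isect[c].prev_bits.push_back((int)i); isect[c].cur_bits.push_back((int)j); ++i; ++j; }
    }
  }

  auto extract = [](uint32_t S, const std::vector<int>& bits) -> uint32_t {
    uint32_t key = 0;
    for (size_t t = 0; t < bits.size(); ++t) key |= ((S >> bits[t]) & 1u) << t;
    return key;
  };

  // forward step: given C[c-1], produce C[c]
  auto forward_step = [&](int c, const std::vector<double>* Cprev,
                          std::vector<double>& Ccur) {
    colcost(c, Ccur);
    if (c == 0 || Cprev == nullptr) return;
    const auto& is = isect[c];
    const uint32_t np = 1u << active[c - 1].size();
    std::vector<double> proj(1u << is.prev_bits.size(), FINF);
    for (uint32_t S = 0; S < np; ++S) {
      uint32_t key = extract(S, is.prev_bits);
      if ((*Cprev)[S] < proj[key]) proj[key] = (*Cprev)[S];
    }
    const uint32_t ncur = (uint32_t)Ccur.size();
    for (uint32_t S = 0; S < ncur; ++S) {
      double p = proj[extract(S, is.cur_bits)];
      Ccur[S] = (p >= FINF) ? FINF : Ccur[S] + p;
    }
  };

  // forward pass with checkpoints
  double total_states = 0;
  for (int c = 0; c < n_cols; ++c) total_states += (double)(1u << active[c].size());
  const bool store_all = total_states <= 2.0e7;
  const int CK = 16;
  std::vector<std::vector<double>> stored(n_cols);  // full arrays (all or checkpoints)
  std::vector<double> cur, prev;
  for (int c = 0; c < n_cols; ++c) {
    forward_step(c, c == 0 ? nullptr : &prev, cur);
    if (store_all || c % CK == 0 || c == n_cols - 1) stored[c] = cur;
    std::swap(prev, cur);
  }

  // prev now holds C[n_cols-1]
  uint32_t bestS = 0;
  double bestv = FINF;
  for (uint32_t S = 0; S < prev.size(); ++S)
    if (prev[S] < bestv) { bestv = prev[S]; bestS = S; }

  // backtrace
  std::vector<uint32_t> chosen(n_cols);
  chosen[n_cols - 1] = bestS;
  for (int c = n_cols - 2; c >= 0; --c) {
    if (stored[c].empty()) {
      // recompute the window from the previous checkpoint
      int c0 = (c / CK) * CK;
      std::vector<double> p2, c2;
      if (c0 > 0) p2 = stored[c0];  // stored checkpoint at c0
      for (int cc = c0; cc <= c; ++cc) {
        if (!stored[cc].empty()) { p2 = stored[cc]; continue; }
        forward_step(cc, &p2, c2);
        stored[cc] = c2;
        std::swap(p2, c2);
      }
    }
    const auto& Cc = stored[c];
    const auto& is = isect[c + 1];
    uint32_t need = extract(chosen[c + 1], is.cur_bits);
    uint32_t arg = 0;
    double av = FINF;
    for (uint32_t S = 0; S < Cc.size(); ++S) {
      if (extract(S, is.prev_bits) != need) continue;
      if (Cc[S] < av) { av = Cc[S]; arg = S; }
    }
    chosen[c] = arg;
    if (!store_all && (c + 1) % CK != 0)
      std::vector<double>().swap(stored[c + 1]);  // free recomputed window columns
  }

  IntegerVector side(n_rows, NA_INTEGER);
  for (int c = 0; c < n_cols; ++c) {
    for (size_t b = 0; b < active[c].size(); ++b) {
      int r = active[c][b];
      if (side[r] == NA_INTEGER) side[r] = (int)((chosen[c] >> b) & 1u);
    }
  }
  return List::create(_["cost"] = (double)bestv, _["side"] = side);
}
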