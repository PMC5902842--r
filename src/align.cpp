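#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Affine-gap local alignment (Gotoh) with full traceback so that matched
// residues -- not just the score -- can be counted. Sequences arrive as
// 1-based integer codes into the substitution matrix. A gap of length L
// costs gap_open + gap_ext * L.
//
// Determinism: the traceback starts at the highest-scoring cell, ties
// broken by lowest target index then lowest query index; within the
// traceback, diagonal moves are preferred over gaps in the target over
// gaps in the query.

namespace {

struct AlnResult {
  double score;
  int matches;
  int q_start, q_end, t_start, t_end;  // 0-based half-open
};

const double NEG_INF = -1e30;

AlnResult local_align_core(const IntegerVector& qv, const IntegerVector& tv,
                           const NumericMatrix& subm, double gap_open,
                           double gap_ext) {
  const int n = qv.size(), m = tv.size();
  const double gopen = gap_open + gap_ext;  // first gap character
  const int na = subm.nrow();
  std::vector<double> subflat(subm.begin(), subm.end());
  std::vector<int> q(qv.begin(), qv.end()), t(tv.begin(), tv.end());
  for (int i = 0; i < n; ++i) q[i] -= 1;
  for (int j = 0; j < m; ++j) t[j] -= 1;
  const double* sub_ptr = subflat.data();

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG_INF), Ecur(m + 1, NEG_INF);
  // trace codes per state matrix
  // TH: 0 stop, 1 diag, 2 from E (gap in query / consume target), 3 from F
  // TE: 0 opened from H, 1 extended; TF likewise
  std::vector<uint8_t> TH((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> TE((size_t)(n + 1) * (m + 1), 0);
  std::vector<uint8_t> TF((size_t)(n + 1) * (m + 1), 0);

  std::vector<double> Fcol(m + 1, NEG_INF);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0;
    Ecur[0] = NEG_INF;
    const double* srow = sub_ptr + (size_t)q[i - 1];  // column-major: row q
    uint8_t* th_row = TH.data() + (size_t)i * (m + 1);
    uint8_t* te_row = TE.data() + (size_t)i * (m + 1);
    uint8_t* tf_row = TF.data() + (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // E: gap consuming target (move along j)
      double e_open = Hcur[j - 1] - gopen;
      double e_ext = Ecur[j - 1] - gap_ext;
      double e = e_open >= e_ext ? e_open : e_ext;
      te_row[j] = e_open >= e_ext ? 0 : 1;
      Ecur[j] = e;
      // F: gap consuming query (move along i)
      double f_open = Hprev[j] - gopen;
      double f_ext = Fcol[j] - gap_ext;
      double f = f_open >= f_ext ? f_open : f_ext;
      tf_row[j] = f_open >= f_ext ? 0 : 1;
      Fcol[j] = f;
      // H
      double diag = Hprev[j - 1] + srow[(size_t)t[j - 1] * na];
      double h = 0.0;
      uint8_t th = 0;
      if (diag >= h) { h = diag; th = 1; }
      if (e > h) { h = e; th = 2; }
      if (f > h) { h = f; th = 3; }
      Hcur[j] = h;
      th_row[j] = th;
      if (h > best || (h == best && (j < bj || (j == bj && i < bi)))) {
        if (h > 0) { best = h; bi = i; bj = j; }
      }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  AlnResult res{best, 0, 0, 0, 0, 0};
  if (best <= 0.0) {
    res.q_start = res.q_end = res.t_start = res.t_end = 0;
    return res;
  }
  // traceback
  int i = bi, j = bj;
  int state = 0;  // 0 = H, 1 = E, 2 = F
  res.q_end = bi;
  res.t_end = bj;
  while (i > 0 && j > 0) {
    const size_t idx = (size_t)i * (m + 1) + j;
    if (state == 0) {
      uint8_t th = TH[idx];
      if (th == 0) break;
      if (th == 1) {
        if (qv[i - 1] == tv[j - 1]) res.matches++;
        --i; --j;
      } else if (th == 2) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      uint8_t te = TE[idx];
      --j;
      state = te == 0 ? 0 : 1;
    } else {
      uint8_t tf = TF[idx];
      --i;
      state = tf == 0 ? 0 : 2;
    }
  }
  res.q_start = i;
  res.t_start = j;
  return res;
}

}  // namespace

// [[Rcpp::export]]
List cpp_local_align(IntegerVector q, IntegerVector t, NumericMatrix sub,
                     double gap_open, double gap_ext) {
  if (q.size() == 0 || t.size() == 0)
    stop("local alignment requires non-empty sequences");
  AlnResult r = local_align_core(q, t, sub, gap_open, gap_ext);
  return List::create(
    _["score"] = r.score, _["matches"] = r.matches,
    _["query_start"] = r.q_start, _["query_end"] = r.q_end,
    _["target_start"] = r.t_start, _["target_end"] = r.t_end);
}

// Batch alignment over candidate (query, target) index pairs; avoids R
// call overhead for all-vs-all comparisons. pairs is a 2-column matrix of
// 1-based indices into qs / ts.
// [[Rcpp::export]]
NumericMatrix cpp_align_pairs(List qs, List ts, IntegerMatrix pairs,
                              NumericMatrix sub, double gap_open,
                              double gap_ext) {
  const int np = pairs.nrow();
  NumericMatrix out(np, 6);
  colnames(out) = CharacterVector::create(
    "score", "matches", "query_start", "query_end", "target_start",
    "target_end");
  for (int p = 0; p < np; ++p) {
    IntegerVector q = qs[pairs(p, 0) - 1];
    IntegerVector t = ts[pairs(p, 1) - 1];
    AlnResult r = local_align_core(q, t, sub, gap_open, gap_ext);
    out(p, 0) = r.score;
    out(p, 1) = r.matches;
    out(p, 2) = r.q_start;
    out(p, 3) = r.q_end;
    out(p, 4) = r.t_start;
    out(p, 5) = r.t_end;
  }
  return out;
}
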