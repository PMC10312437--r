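#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive placement scan of one read byte-vector over a (concatenated)
// reference byte-vector. For every window start the banded DP tracks the
// minimal number of mismatches after j read bases using d internal
// reference deletions (insertions are not modeled). Returns one row per
// start that admits a placement with <= max_mm mismatches, keeping the
// (fewest edits, then fewest deletions) alignment for that start.
// [[Rcpp::export]]
DataFrame scan_concat_cpp(IntegerVector rb, IntegerVector cat,
                          int max_mm, int max_del) {
  const int m = rb.size();
  const int n = cat.size();
  const int INF = 1 << 28;
  std::vector<int> starts, dels, mms;
  const int ns = n - m - max_del + 1;
  std::vector<int> E(max_del + 1);
  const int *R = rb.begin();
  const int *C = cat.begin();
  for (int s = 0; s < ns; ++s) {
    E[0] = 0;
    for (int d = 1; d <= max_del; ++d) E[d] = INF;
    int best = 0;
    const int *W = C + s;
    for (int j = 0; j < m; ++j) {
      if (j >= 1) {
        // deletion between read bases j-1 and j (internal only)
        for (int d = max_del; d >= 1; --d)
          if (E[d - 1] < E[d]) E[d] = E[d - 1];
      }
      best = INF;
      const int q = R[j];
      for (int d = 0; d <= max_del; ++d) {
        if (E[d] < INF) E[d] += (W[j + d] != q);
        if (E[d] < best) best = E[d];
      }
      if (best > max_mm) break;
    }
    if (best > max_mm) continue;
    int bd = -1, bscore = INF;
    for (int d = 0; d <= max_del; ++d) {
      if (E[d] <= max_mm && E[d] + d < bscore) {
        bscore = E[d] + d;
        bd = d;
      }
    }
    if (bd >= 0) {
      starts.push_back(s);
      dels.push_back(bd);
      mms.push_back(E[bd]);
    }
  }
  return DataFrame::create(_["start"] = starts, _["n_del"] = dels,
                           _["n_mm"] = mms);
}
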