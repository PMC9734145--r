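#include <Rcpp.h>
using namespace Rcpp;

// Global unit-cost alignment of a performed pitch sequence against the
// score's pitch sequence. Suffix-cost dynamic programme followed by a
// forward walk so ties resolve left-to-right with the fixed preference
// match > substitution > missing (score skip) > extra (performance skip).
//
// Returned op codes: 0 match, 1 substituted, 2 missing, 3 extra.
// [[Rcpp::export]]
List align_cpp(IntegerVector score, IntegerVector perf) {
  const int n = score.size(), m = perf.size();
  // D[i][j] = edit distance between score[i..) and perf[j..)
  std::vector<int> D((n + 1) * (m + 1));
  const int W = m + 1;
  for (int j = 0; j <= m; ++j) D[n * W + j] = m - j;
  for (int i = n - 1; i >= 0; --i) {
    D[i * W + m] = n - i;
    for (int j = m - 1; j >= 0; --j) {
      int diag = D[(i + 1) * W + j + 1] + (score[i] == perf[j] ? 0 : 1);
      int del = D[(i + 1) * W + j] + 1;   // score note missing
      int ins = D[i * W + j + 1] + 1;     // extra performed note
      int best = diag < del ? diag : del;
      if (ins < best) best = ins;
      D[i * W + j] = best;
    }
  }
  std::vector<int> op, si, pi;
  op.reserve(n + m); si.reserve(n + m); pi.reserve(n + m);
  int i = 0, j = 0;
  while (i < n || j < m) {
    int here = D[i * W + j];
    if (i < n && j < m && score[i] == perf[j] &&
        D[(i + 1) * W + j + 1] == here) {
      op.push_back(0); si.push_back(i); pi.push_back(j); ++i; ++j;
    } else if (i < n && j < m && D[(i + 1) * W + j + 1] + 1 == here) {
      op.push_back(1); si.push_back(i); pi.push_back(j); ++i; ++j;
    } else if (i < n && D[(i + 1) * W + j] + 1 == here) {
      op.push_back(2); si.push_back(i); pi.push_back(-1); ++i;
    } else {
      op.push_back(3); si.push_back(-1); pi.push_back(j); ++j;
    }
  }
  return List::create(_["edit_distance"] = D[0],
                      _["op"] = wrap(op), _["score_index"] = wrap(si),
                      _["perf_index"] = wrap(pi));
}
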