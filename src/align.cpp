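// Affine-gap local alignment (Gotoh) with full traceback.
//
// Scoring: match / mismatch per aligned pair ('N' never matches), a gap of
// length L costs gap_open + L * gap_extend. Tie-breaking is deterministic:
// among equal-scoring end cells the first reached in row-major order wins
// (smallest query end, then target end), and the traceback prefers a
// diagonal step over a gap step.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_align_local")]]
List cpp_align_local(std::string q, std::string t, double match,
                     double mismatch, double gap_open, double gap_extend) {
  const int m = q.size(), n = t.size();
  const double NEG = -1e18;
  const size_t W = (size_t)n + 1;
  std::vector<double> H((m + 1) * W, 0.0);
  std::vector<double> E((m + 1) * W, NEG); // gap in query (left move)
  std::vector<double> F((m + 1) * W, NEG); // gap in target (up move)

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const size_t r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      E[r + j] = std::max(H[r + j - 1] - gap_open - gap_extend,
                          E[r + j - 1] - gap_extend);
      F[r + j] = std::max(H[p + j] - gap_open - gap_extend,
                          F[p + j] - gap_extend);
      const char qc = q[i - 1], tc = t[j - 1];
      const double s =
          (qc == tc && qc != 'N' && qc != 'n') ? match : mismatch;
      double h = 0.0;
      const double diag = H[p + j - 1] + s;
      if (diag > h) h = diag;
      if (F[r + j] > h) h = F[r + j];
      if (E[r + j] > h) h = E[r + j];
      H[r + j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  // traceback from (bi, bj); preference diag > up (gap in target) > left
  std::string qa, ta;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 2 = E, 3 = F
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    const size_t r = (size_t)i * W, p = (size_t)(i - 1) * W;
    if (state == 0) {
      if (H[r + j] <= eps) break; // local alignment start
      const char qc = (i > 0) ? q[i - 1] : 0, tc = (j > 0) ? t[j - 1] : 0;
      const double s =
          (qc == tc && qc != 'N' && qc != 'n') ? match : mismatch;
      if (i > 0 && j > 0 && std::abs(H[r + j] - (H[p + j - 1] + s)) < eps) {
        qa.push_back(qc);
        ta.push_back(tc);
        --i; --j;
      } else if (i > 0 && std::abs(H[r + j] - F[r + j]) < eps) {
        state = 3;
      } else {
        state = 2;
      }
    } else if (state == 3) { // gap in target: consume query base
      const double open = H[p + j] - gap_open - gap_extend;
      qa.push_back(q[i - 1]);
      ta.push_back('-');
      const bool was_open = std::abs(F[r + j] - open) < eps;
      --i;
      if (was_open) state = 0;
    } else { // state == 2, gap in query: consume target base
      const double open = H[r + j - 1] - gap_open - gap_extend;
      qa.push_back('-');
      ta.push_back(t[j - 1]);
      const bool was_open = std::abs(E[r + j] - open) < eps;
      --j;
      if (was_open) state = 0;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());

  // 0-based half-open coordinates of the aligned region
  int q_used = 0, t_used = 0;
  for (char c : qa) if (c != '-') ++q_used;
  for (char c : ta) if (c != '-') ++t_used;
  const int q_start = (best > 0) ? bi - q_used : 0;
  const int t_start = (best > 0) ? bj - t_used : 0;
  return List::create(
      _["score"] = best, _["query_aln"] = qa, _["target_aln"] = ta,
      _["query_start"] = q_start, _["query_end"] = (best > 0) ? bi : 0,
      _["target_start"] = t_start, _["target_end"] = (best > 0) ? bj : 0);
}
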