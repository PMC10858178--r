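#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// A gap of length g costs gap_open + (g - 1) * gap_extend (both negative).
// Deterministic tie-breaking: diagonal (M) preferred over up (gap in b,
// consumes a) preferred over left (gap in a, consumes b).

static const double NEG = -1e18;

// [[Rcpp::export]]
List cpp_nw_align(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  int W = m + 1;
  // score + predecessor-state matrices for states M=0, X=1 (up), Y=2 (left)
  std::vector<double> S(3 * (size_t)(n + 1) * W, NEG);
  std::vector<signed char> P(3 * (size_t)(n + 1) * W, -1);
#define IDX(s, i, j) (((size_t)(s) * (n + 1) + (i)) * W + (j))
  S[IDX(0, 0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    S[IDX(1, i, 0)] = gap_open + (i - 1) * gap_extend;
    P[IDX(1, i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    S[IDX(2, 0, j)] = gap_open + (j - 1) * gap_extend;
    P[IDX(2, 0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume a[i-1], b[j-1]
      double sub = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = S[IDX(0, i - 1, j - 1)];
      int bs = 0;
      if (S[IDX(1, i - 1, j - 1)] > best) { best = S[IDX(1, i - 1, j - 1)]; bs = 1; }
      if (S[IDX(2, i - 1, j - 1)] > best) { best = S[IDX(2, i - 1, j - 1)]; bs = 2; }
      if (best > NEG / 2) {
        S[IDX(0, i, j)] = best + sub;
        P[IDX(0, i, j)] = (signed char)bs;
      }
      // X (up): consume a[i-1] against a gap
      double xo = S[IDX(0, i - 1, j)] + gap_open;
      double xx = S[IDX(1, i - 1, j)] + gap_extend;
      double xy = S[IDX(2, i - 1, j)] + gap_open;
      best = xo; bs = 0;
      if (xx > best) { best = xx; bs = 1; }
      if (xy > best) { best = xy; bs = 2; }
      if (best > NEG / 2) { S[IDX(1, i, j)] = best; P[IDX(1, i, j)] = (signed char)bs; }
      // Y (left): consume b[j-1] against a gap
      double yo = S[IDX(0, i, j - 1)] + gap_open;
      double yx = S[IDX(1, i, j - 1)] + gap_open;
      double yy = S[IDX(2, i, j - 1)] + gap_extend;
      best = yo; bs = 0;
      if (yx > best) { best = yx; bs = 1; }
      if (yy > best) { best = yy; bs = 2; }
      if (best > NEG / 2) { S[IDX(2, i, j)] = best; P[IDX(2, i, j)] = (signed char)bs; }
    }
  }
  // final state: M preferred, then X, then Y
  int st = 0;
  double sc = S[IDX(0, n, m)];
  if (S[IDX(1, n, m)] > sc) { sc = S[IDX(1, n, m)]; st = 1; }
  if (S[IDX(2, n, m)] > sc) { sc = S[IDX(2, n, m)]; st = 2; }
  std::string oa, ob;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev = P[IDX(st, i, j)];
    if (st == 0) { oa += a[i - 1]; ob += b[j - 1]; --i; --j; }
    else if (st == 1) { oa += a[i - 1]; ob += '-'; --i; }
    else { oa += '-'; ob += b[j - 1]; --j; }
    st = prev;
  }
#undef IDX
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["aligned1"] = oa, _["aligned2"] = ob, _["score"] = sc);
}
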