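#include <Rcpp.h>
using namespace Rcpp;

// 3' partial-sum trimming rule: S(i) = sum_{j>=i} (q_j - cutoff); cut at the
// position minimising S (ties -> smaller i, i.e. trim more); no cut if the
// minimum is non-negative. Returns the kept prefix length.
static int cut_point(const int* q, int n, int cutoff) {
  long best = 0;
  int besti = n;
  long s = 0;
  for (int i = n - 1; i >= 0; --i) {
    s += q[i] - cutoff;
    if (s <= best) { best = s; besti = i; }
  }
  return (best < 0) ? besti : n;
}

// [[Rcpp::export]]
int cpp_trim_cut(IntegerVector quals, int cutoff) {
  return cut_point(quals.begin(), quals.size(), cutoff);
}

// Batch trimming of paired reads; qualities are Phred+33 strings.
// [[Rcpp::export]]
List cpp_trim_pairs(CharacterVector s1, CharacterVector q1,
                    CharacterVector s2, CharacterVector q2,
                    int cutoff, int min_len) {
  int n = s1.size();
  if (q1.size() != n || s2.size() != n || q2.size() != n)
    stop("mate vectors must have equal length");
  CharacterVector ts1(n), tq1(n), ts2(n), tq2(n);
  LogicalVector keep(n);
  double bases_in = 0, bases_kept = 0;
  std::vector<int> buf;
  for (int r = 0; r < n; ++r) {
    int kept_len[2];
    for (int m = 0; m < 2; ++m) {
      std::string sq = as<std::string>(m == 0 ? s1[r] : s2[r]);
      std::string ql = as<std::string>(m == 0 ? q1[r] : q2[r]);
      if (sq.size() != ql.size())
        stop("sequence/quality length mismatch in record %d", r + 1);
      int L = sq.size();
      bases_in += L;
      buf.resize(L);
      for (int i = 0; i < L; ++i) buf[i] = (int)ql[i] - 33;
      int c = cut_point(buf.data(), L, cutoff);
      kept_len[m] = c;
      std::string osq = sq.substr(0, c), oql = ql.substr(0, c);
      if (m == 0) { ts1[r] = osq; tq1[r] = oql; }
      else        { ts2[r] = osq; tq2[r] = oql; }
    }
    keep[r] = (kept_len[0] >= min_len) && (kept_len[1] >= min_len);
    if (keep[r]) bases_kept += kept_len[0] + kept_len[1];
  }
  return List::create(_["seq1"] = ts1, _["qual1"] = tq1,
                      _["seq2"] = ts2, _["qual2"] = tq2,
                      _["keep"] = keep,
                      _["bases_in"] = bases_in, _["bases_kept"] = bases_kept);
}
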