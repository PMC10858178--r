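#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Paired-end read simulation from a weighted set of source sequences
// (haplotype contigs). Fragment lengths are normal, truncated below at
// read_len and above at the source length; fragment starts are uniform.
// Mate 1 is the fragment head, mate 2 the reverse complement of the
// fragment tail. Substitution errors are per-base Bernoulli; qualities
// decay linearly from q_start to q_floor with Gaussian jitter, clipped to
// [2, 41]. Uses R's RNG, so results are governed by set.seed().

static inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default: return 'N';
  }
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
List cpp_simulate_pairs(CharacterVector sources, NumericVector weights,
                        int n_pairs, int read_len, double frag_mean,
                        double frag_sd, double error_rate,
                        double q_start, double q_floor, double q_sd) {
  int ns = sources.size();
  if (ns == 0) stop("no source sequences");
  if (weights.size() != ns) stop("weights must match sources");
  std::vector<std::string> src(ns);
  std::vector<int> slen(ns);
  for (int i = 0; i < ns; ++i) {
    src[i] = as<std::string>(sources[i]);
    slen[i] = (int)src[i].size();
    if (slen[i] < read_len) stop("source %d shorter than read_len", i + 1);
  }
  std::vector<double> cw(ns);
  double tot = 0;
  for (int i = 0; i < ns; ++i) { tot += weights[i]; cw[i] = tot; }
  if (tot <= 0) stop("weights must sum to a positive value");

  CharacterVector seq1(n_pairs), qual1(n_pairs), seq2(n_pairs), qual2(n_pairs);
  IntegerVector hap(n_pairs), fstart(n_pairs), fend(n_pairs);

  std::string m1(read_len, 'N'), m2(read_len, 'N');
  std::string ql(read_len, '!');
  double slope = (read_len > 1) ? (q_start - q_floor) / (read_len - 1) : 0.0;

  for (int p = 0; p < n_pairs; ++p) {
    double u = unif_rand() * tot;
    int h = 0;
    while (h < ns - 1 && u > cw[h]) ++h;
    int hl = slen[h];
    int fl = (int)::round(norm_rand() * frag_sd + frag_mean);
    if (fl < read_len) fl = read_len;
    if (fl > hl) fl = hl;
    int start = (int)(unif_rand() * (hl - fl + 1));
    if (start > hl - fl) start = hl - fl;
    const std::string& s = src[h];
    for (int i = 0; i < read_len; ++i) m1[i] = s[start + i];
    int tail0 = start + fl - read_len;
    for (int i = 0; i < read_len; ++i)
      m2[i] = comp_char(s[tail0 + read_len - 1 - i]);
    for (int m = 0; m < 2; ++m) {
      std::string& rd = m == 0 ? m1 : m2;
      if (error_rate > 0) {
        for (int i = 0; i < read_len; ++i) {
          if (unif_rand() < error_rate) {
            int b = base_code(rd[i]);
            if (b >= 0) {
              int nb = (b + 1 + (int)(unif_rand() * 3.0)) & 3;
              if (nb == b) nb = (b + 1) & 3; // guard against unif_rand()==1
              rd[i] = BASES[nb];
            }
          }
        }
      }
      for (int i = 0; i < read_len; ++i) {
        double q = q_start - slope * i + norm_rand() * q_sd;
        int iq = (int)::round(q);
        if (iq < 2) iq = 2;
        if (iq > 41) iq = 41;
        ql[i] = (char)(33 + iq);
      }
      if (m == 0) { seq1[p] = m1; qual1[p] = ql; }
      else        { seq2[p] = m2; qual2[p] = ql; }
    }
    hap[p] = h + 1;
    fstart[p] = start;
    fend[p] = start + fl;
  }
  return List::create(_["seq1"] = seq1, _["qual1"] = qual1,
                      _["seq2"] = seq2, _["qual2"] = qual2,
                      _["source"] = hap, _["frag_start"] = fstart,
                      _["frag_end"] = fend);
}
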