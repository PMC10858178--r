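#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
#include <algorithm>
#include <climits>
using namespace Rcpp;

// Seed-and-chain split aligner. The index stores every k-mer position of the
// forward reference strand; reads are queried as-is and as their reverse
// complement. Candidate placements are ungapped diagonals; a read is reported
// as a full alignment when one diagonal covers >= full_cov of the read at an
// acceptable mismatch rate, otherwise as the best-scoring two-segment
// (prefix + suffix) partition across two diagonals (a split), else unmapped.
// Scoring: match +1, mismatch -1, split penalty applied once per split.
// Junction ties are resolved toward the largest prefix (microhomology bases
// are absorbed by the first segment).

namespace {

struct KmerIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  std::vector<long long> offsets; // size n+1; global start of each contig
  std::unordered_map<uint64_t, std::vector<long long> > pos;
};

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp_char(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

inline int find_contig(const KmerIndex& I, long long g) {
  // largest c with offsets[c] <= g
  int lo = 0, hi = (int)I.names.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (I.offsets[mid] <= g) lo = mid; else hi = mid - 1;
  }
  return lo;
}

struct CandEval {
  int strand;      // 0 = '+', 1 = '-'
  long long diag;  // global ref position of read coordinate 0 (oriented)
  int contig;
  int vlo, vhi;            // valid read-coordinate range [vlo, vhi)
  std::vector<int> ps;     // prefix sums of +1/-1 per-base scores
  std::vector<int> pm;     // prefix mismatch counts
  long full_score;
  bool full_ok;
};

} // namespace

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be in [2, 31]");
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  long long off = 0;
  uint64_t mask = (((uint64_t)1) << (2 * k)) - 1;
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    std::string nm = as<std::string>(names[c]);
    if ((int)s.size() < k) {
      delete idx;
      stop("contig '%s' is shorter than k = %d", nm.c_str(), k);
    }
    idx->names.push_back(nm);
    idx->offsets.push_back(off);
    uint64_t code = 0;
    int run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int b = base_code(s[i]);
      if (b < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint64_t)b) & mask;
      ++run;
      if (run >= k) idx->pos[code].push_back(off + (long long)i - k + 1);
    }
    idx->seqs.push_back(s);
    off += (long long)s.size();
  }
  idx->offsets.push_back(off);
  XPtr<KmerIndex> p(idx, true);
  return p;
}

// [[Rcpp::export]]
DataFrame cpp_kmer_lookup(SEXP ptr, std::string kmer) {
  XPtr<KmerIndex> idx(ptr);
  const KmerIndex& I = *idx;
  if ((int)kmer.size() != I.k) stop("query length must equal index k");
  uint64_t code = 0;
  for (size_t i = 0; i < kmer.size(); ++i) {
    int b = base_code(kmer[i]);
    if (b < 0) stop("query contains a non-ACGT base");
    code = (code << 2) | (uint64_t)b;
  }
  std::vector<int> contig;
  std::vector<double> p;
  std::unordered_map<uint64_t, std::vector<long long> >::const_iterator it =
      I.pos.find(code);
  if (it != I.pos.end()) {
    for (size_t i = 0; i < it->second.size(); ++i) {
      long long g = it->second[i];
      int c = find_contig(I, g);
      contig.push_back(c + 1);
      p.push_back((double)(g - I.offsets[c]));
    }
  }
  return DataFrame::create(_["contig"] = contig, _["pos"] = p);
}

// [[Rcpp::export]]
List cpp_index_info(SEXP ptr) {
  XPtr<KmerIndex> idx(ptr);
  NumericVector lens(idx->names.size());
  CharacterVector nms(idx->names.size());
  for (size_t i = 0; i < idx->names.size(); ++i) {
    nms[i] = idx->names[i];
    lens[i] = (double)(idx->offsets[i + 1] - idx->offsets[i]);
  }
  return List::create(_["k"] = idx->k, _["names"] = nms, _["lengths"] = lens);
}

// [[Rcpp::export]]
DataFrame cpp_align_batch(SEXP ptr, CharacterVector reads,
                          int min_seg, double max_mm_rate, int margin,
                          int split_penalty, int seed_step,
                          int min_split_score, double full_cov) {
  XPtr<KmerIndex> idx(ptr);
  const KmerIndex& I = *idx;
  const int k = I.k;
  const long long total = I.offsets.back();
  const int MAXC = 12;     // candidate diagonals evaluated per read
  const int MAX_HITS = 32; // skip k-mers more repetitive than this
  int n = reads.size();

  IntegerVector type(n);
  IntegerVector a_contig(n, NA_INTEGER), a_start(n, NA_INTEGER),
      a_end(n, NA_INTEGER), a_rstart(n, NA_INTEGER), a_rend(n, NA_INTEGER),
      a_mm(n, NA_INTEGER);
  IntegerVector b_contig(n, NA_INTEGER), b_start(n, NA_INTEGER),
      b_end(n, NA_INTEGER), b_rstart(n, NA_INTEGER), b_rend(n, NA_INTEGER),
      b_mm(n, NA_INTEGER);
  CharacterVector a_strand(n, NA_STRING), b_strand(n, NA_STRING);
  IntegerVector junction(n, NA_INTEGER), score(n, NA_INTEGER),
      secondary(n, NA_INTEGER);
  LogicalVector uniq(n, NA_LOGICAL);

  std::vector<CandEval> ev;
  for (int r = 0; r < n; ++r) {
    type[r] = 0;
    std::string rd = as<std::string>(reads[r]);
    int L = (int)rd.size();
    if (L < k) continue;
    std::string rc(L, 'N');
    for (int i = 0; i < L; ++i) rc[L - 1 - i] = comp_char(rd[i]);

    // seed both orientations, tally diagonals
    std::unordered_map<uint64_t, int> tally;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = strand ? rc : rd;
      for (int q = 0; q <= L - k; q += seed_step) {
        int qq = q;
        bool last_extra = false;
        if (q + seed_step > L - k && q != L - k) {
          // also probe the final k-mer so 3' flanks always carry a seed
          last_extra = true;
        }
        for (int pass = 0; pass < (last_extra ? 2 : 1); ++pass) {
          if (pass == 1) qq = L - k;
          uint64_t code = 0;
          bool ok = true;
          for (int j = 0; j < k; ++j) {
            int b = base_code(s[qq + j]);
            if (b < 0) { ok = false; break; }
            code = (code << 2) | (uint64_t)b;
          }
          if (!ok) continue;
          std::unordered_map<uint64_t, std::vector<long long> >::const_iterator
              it = I.pos.find(code);
          if (it == I.pos.end()) continue;
          if ((int)it->second.size() > MAX_HITS) continue;
          for (size_t h = 0; h < it->second.size(); ++h) {
            long long diag = it->second[h] - qq;
            uint64_t key = ((uint64_t)(diag + L) << 1) | (uint64_t)strand;
            tally[key]++;
          }
        }
      }
    }
    if (tally.empty()) continue;

    std::vector<std::pair<int, uint64_t> > cands;
    cands.reserve(tally.size());
    for (std::unordered_map<uint64_t, int>::iterator it = tally.begin();
         it != tally.end(); ++it)
      cands.push_back(std::make_pair(it->second, it->first));
    std::sort(cands.begin(), cands.end(),
              [](const std::pair<int, uint64_t>& x,
                 const std::pair<int, uint64_t>& y) {
                if (x.first != y.first) return x.first > y.first;
                return x.second < y.second;
              });
    if ((int)cands.size() > MAXC) cands.resize(MAXC);

    ev.clear();
    for (size_t ci = 0; ci < cands.size(); ++ci) {
      uint64_t key = cands[ci].second;
      int strand = (int)(key & 1);
      long long diag = (long long)(key >> 1) - L;
      // the reference window [diag, diag + L) may straddle a contig
      // boundary (a junction read seeded at a contig end does exactly
      // that); evaluate the candidate against every contig it overlaps
      long long glo = std::max<long long>(diag, 0);
      long long ghi = std::min<long long>(diag + L, total);
      if (glo >= ghi) continue;
      int c_lo = find_contig(I, glo);
      int c_hi = find_contig(I, ghi - 1);
      for (int c = c_lo; c <= c_hi; ++c) {
      long long coff = I.offsets[c], cend = I.offsets[c + 1];
      // valid read-coordinate range whose reference positions fall inside
      // the contig; read coordinate i maps to diag + i (+) or
      // diag + L - 1 - i (-)
      int vlo, vhi;
      if (strand == 0) {
        vlo = (int)std::max<long long>(0, coff - diag);
        vhi = (int)std::min<long long>((long long)L, cend - diag);
      } else {
        vlo = (int)std::max<long long>(0, diag + (long long)L - cend);
        vhi = (int)std::min<long long>((long long)L, diag + (long long)L - coff);
      }
      if (vhi - vlo < k) continue;
      CandEval e;
      e.strand = strand; e.diag = diag; e.contig = c;
      e.vlo = vlo; e.vhi = vhi;
      e.ps.assign(L + 1, 0);
      e.pm.assign(L + 1, 0);
      const std::string& cs = I.seqs[c];
      for (int i = 0; i < L; ++i) {
        int sc, mm;
        if (i < vlo || i >= vhi) { sc = -1000; mm = 1; }
        else {
          char refc = strand
              ? cs[(size_t)(diag + (long long)L - 1 - i - coff)]
              : cs[(size_t)(diag + i - coff)];
          char qc = strand ? comp_char(rd[i]) : rd[i];
          bool m = (qc == refc) && base_code(qc) >= 0;
          sc = m ? 1 : -1;
          mm = m ? 0 : 1;
        }
        e.ps[i + 1] = e.ps[i] + sc;
        e.pm[i + 1] = e.pm[i] + mm;
      }
      int vlen = e.vhi - e.vlo;
      int vmm = e.pm[e.vhi] - e.pm[e.vlo];
      e.full_score = (long)vlen - 2L * vmm;
      e.full_ok = (vlen >= (int)std::ceil(full_cov * L)) &&
                  ((double)vmm <= max_mm_rate * vlen);
      ev.push_back(e);
      }
    }
    if (ev.empty()) continue;
    int nev = (int)ev.size();

    // hypotheses: every candidate as a full placement, plus the best split
    // for every ordered candidate pair (prefix A, suffix B)
    std::vector<long> hypScore;
    std::vector<long> hypTag; // cand index, or 1e6 + a*1000 + b for splits
    int bestFull = -1;
    for (int a = 0; a < nev; ++a) {
      hypScore.push_back(ev[a].full_score);
      hypTag.push_back(a);
      if (ev[a].full_ok &&
          (bestFull < 0 || ev[a].full_score > ev[bestFull].full_score))
        bestFull = a;
    }
    int bsA = -1, bsB = -1, bsJ = -1;
    long bsScore = LONG_MIN;
    if (L >= 2 * min_seg) {
      for (int a = 0; a < nev; ++a) {
        if (ev[a].vlo != 0) continue;
        for (int b = 0; b < nev; ++b) {
          if (b == a || ev[b].vhi != L) continue;
          int jlo = std::max(min_seg, ev[b].vlo);
          int jhi = std::min(L - min_seg, ev[a].vhi);
          long best = LONG_MIN;
          int bestj = -1;
          for (int j = jlo; j <= jhi; ++j) {
            int mmA = ev[a].pm[j];
            int mmB = ev[b].pm[L] - ev[b].pm[j];
            if ((double)mmA > max_mm_rate * j) continue;
            if ((double)mmB > max_mm_rate * (L - j)) continue;
            long sc = (long)ev[a].ps[j] + (long)(ev[b].ps[L] - ev[b].ps[j]) -
                      (long)split_penalty;
            if (sc >= best) { best = sc; bestj = j; } // ties -> larger j
          }
          if (bestj >= 0) {
            long tag = 1000000L + (long)a * 1000L + b;
            hypScore.push_back(best);
            hypTag.push_back(tag);
            if (best > bsScore) { bsScore = best; bsA = a; bsB = b; bsJ = bestj; }
          }
        }
      }
    }

    long chosenTag, chosenScore;
    if (bestFull >= 0) {
      chosenTag = bestFull;
      chosenScore = ev[bestFull].full_score;
      type[r] = 1;
    } else if (bsA >= 0 && bsScore >= min_split_score) {
      chosenTag = 1000000L + (long)bsA * 1000L + bsB;
      chosenScore = bsScore;
      type[r] = 2;
    } else {
      continue;
    }

    long sec = LONG_MIN;
    bool skipped = false;
    for (size_t h = 0; h < hypScore.size(); ++h) {
      if (!skipped && hypTag[h] == chosenTag) { skipped = true; continue; }
      if (hypScore[h] > sec) sec = hypScore[h];
    }
    score[r] = (int)chosenScore;
    if (sec == LONG_MIN) {
      uniq[r] = true; // no competing placement
    } else {
      secondary[r] = (int)sec;
      uniq[r] = (chosenScore - sec) >= margin;
    }

    if (type[r] == 1) {
      const CandEval& e = ev[bestFull];
      a_contig[r] = e.contig + 1;
      a_rstart[r] = e.vlo;
      a_rend[r] = e.vhi;
      long long coff = I.offsets[e.contig];
      if (e.strand == 0) {
        a_start[r] = (int)(e.diag + e.vlo - coff);
        a_end[r] = (int)(e.diag + e.vhi - coff);
      } else {
        a_start[r] = (int)(e.diag + (long long)L - e.vhi - coff);
        a_end[r] = (int)(e.diag + (long long)L - e.vlo - coff);
      }
      a_strand[r] = e.strand ? "-" : "+";
      a_mm[r] = e.pm[e.vhi] - e.pm[e.vlo];
    } else {
      const CandEval& A = ev[bsA];
      const CandEval& B = ev[bsB];
      int j = bsJ;
      long long offA = I.offsets[A.contig], offB = I.offsets[B.contig];
      a_contig[r] = A.contig + 1;
      a_rstart[r] = 0; a_rend[r] = j;
      if (A.strand == 0) {
        a_start[r] = (int)(A.diag - offA);
        a_end[r] = (int)(A.diag + j - offA);
      } else {
        a_start[r] = (int)(A.diag + (long long)L - j - offA);
        a_end[r] = (int)(A.diag + (long long)L - offA);
      }
      a_strand[r] = A.strand ? "-" : "+";
      a_mm[r] = A.pm[j];
      b_contig[r] = B.contig + 1;
      b_rstart[r] = j; b_rend[r] = L;
      if (B.strand == 0) {
        b_start[r] = (int)(B.diag + j - offB);
        b_end[r] = (int)(B.diag + L - offB);
      } else {
        b_start[r] = (int)(B.diag - offB);
        b_end[r] = (int)(B.diag + (long long)L - j - offB);
      }
      b_strand[r] = B.strand ? "-" : "+";
      b_mm[r] = B.pm[L] - B.pm[j];
      junction[r] = j;
    }
  }

  return DataFrame::create(
      _["type"] = type,
      _["contig_a"] = a_contig, _["ref_start_a"] = a_start,
      _["ref_end_a"] = a_end, _["strand_a"] = a_strand,
      _["read_start_a"] = a_rstart, _["read_end_a"] = a_rend,
      _["mismatches_a"] = a_mm,
      _["contig_b"] = b_contig, _["ref_start_b"] = b_start,
      _["ref_end_b"] = b_end, _["strand_b"] = b_strand,
      _["read_start_b"] = b_rstart, _["read_end_b"] = b_rend,
      _["mismatches_b"] = b_mm,
      _["junction_offset"] = junction,
      _["score"] = score, _["secondary_score"] = secondary,
      _["unique"] = uniq,
      _["stringsAsFactors"] = false);
}
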