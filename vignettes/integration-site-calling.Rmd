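---
title: "Split-read discovery of provirus integration sites"
author: "proviscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-read discovery of provirus integration sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A retroviral transgene (a GFP-tagged murine-leukemia-virus provirus carried
in a mouse line) integrates into the host genome as proviral DNA flanked by
terminal repeats. Two questions drive this package:

1. **Where is the provirus integrated?** Whole-genome paired-end sequencing
   of host DNA, mapped against the host assembly *plus* the provirus
   sequence, yields *split (chimeric) reads*: reads whose prefix aligns to a
   host chromosome and whose suffix aligns to the provirus (or vice versa).
   A cluster of such *trans* splits pinpoints an integration breakpoint.
   A germline insertion present on one allele should be supported by roughly
   half the local read depth; a somatic insertion present in a small
   fraction of cells leaves only one or a few split reads.
2. **Is the provirus hypermutated?** Cytidine deaminases of the APOBEC3
   family attack retroviral replication intermediates and leave a
   characteristic excess of plus-strand G→A substitutions. Sanger-sequenced
   plasmid clones of an RT-PCR amplicon, compared against the amplicon
   reference, quantify this: per-clone substitution counts, the substitution
   spectrum, and per-mouse means.

`proviscan` implements both analyses as a reusable, fully tested pipeline,
together with a synthetic-data generator that emulates the sequencing
experiment so that every stage can be validated against known truth.

## The procedure

### Quality trimming

Reads are trimmed from the 3' end with the standard partial-sum rule: with
Phred scores $q_j$ and cutoff $c$ (default 20), define
$S(i) = \sum_{j \ge i} (q_j - c)$ and cut at the position minimising $S$,
provided that minimum is negative. Ties are broken toward the smaller
position, i.e. trimming more — conservative toward low quality, and
documented so the exhaustive test oracle matches exactly. Pairs in which
either trimmed mate is shorter than 20 bp are discarded. Adapter handling is
reduced to exact-match clipping; the synthetic reads carry no adapters, and
error-tolerant adapter alignment is out of scope.

### Split alignment

The aligner is a seed-and-chain chimeric mapper over an exact k-mer index
(default $k = 21$) of the forward strand of the combined host + provirus
reference; reads are queried as-is and as their reverse complement. Seeds
vote for (contig, strand, diagonal) candidates; candidates whose reference
window straddles a contig boundary are evaluated against every contig they
overlap, clipped to the contig (this is precisely the situation of a
junction read seeded at the provirus end).

* A **full** alignment is reported when one diagonal covers ≥ 95% of the
  read at a mismatch rate ≤ 0.05.
* Otherwise the best **split** is reported: a prefix segment on one
  diagonal plus a suffix segment on another (any contigs/strands), each at
  least `min_seg` = 25 bp, maximising the score (match +1, mismatch −1,
  split penalty −2) under a per-segment mismatch-rate cap. Segments are
  ungapped — the synthetic data contain no indels, a documented limitation.
* Junction ties are resolved by assigning microhomology bases to the first
  segment (the junction offset is pushed to the largest value at which the
  prefix still matches), so breakpoints are reported deterministically.
* An alignment is **unique** iff its score exceeds the best competing
  placement by the uniqueness margin (default 5 score units). This is an
  explicit, testable stand-in for the "uniquely mapped" flag of production
  aligners, whose internal criteria are tool-specific.

Reads with no qualifying placement are unmapped; a random 150-mer has
essentially no chance of a spurious 21-mer seed in a megabase genome.

### Integration calling

Uniquely mapped splits with exactly one segment on the provirus contig and
one on a host contig (*trans* splits) are extracted. Each is annotated with:

* the **host breakpoint** — the host base adjacent to the junction (for a
  host-side prefix segment, the last host base before the provirus; for a
  host-side suffix segment, the first host base after it). Whether a
  published split coordinate refers to breakpoint estimates or segment
  starts is ambiguous in general, so both the breakpoint and the full
  segment interval are emitted;
* whether the provirus segment **covers a terminal UTR** — split reads
  through the true integration junction must touch the 5' or 3' end of the
  provirus, while splits into its interior are artifacts of partial
  integrations or cross-mapping between related endogenous retroviral
  sequences;
* whether the host contig is a **placed** chromosome or an unplaced
  scaffold.

Breakpoints are clustered per contig by single linkage with a 300 bp gap
(about twice the read length; the germline evidence in a real library
spans on the order of 100 bp). Each cluster becomes one call: support =
member reads, breakpoint = median member breakpoint (ties toward the lower
coordinate).

Two discard rules are applied, and discarded calls are retained with their
status so the filtering is auditable:

* `discarded_unplaced`: the call sits on an unplaced scaffold. The source
  procedure's phrasing is ambiguous about whether this applies only to
  singular splits; we apply it to all calls and record the status per call,
  so the alternative reading is recoverable from the output.
* `discarded_no_utr`: the call is singular (support 1) **and** no member
  covers a terminal UTR.

"Strong evidence" is operationalised as `status = "pass"` with no further
support threshold — a single split that covers a UTR on a placed chromosome
passes, which is exactly the signature of a low-fraction somatic insertion.
Germline versus somatic labels are *not* assigned; the support/depth ratio
in the report is the caller's only hint, since that inference is contextual.

### Coverage

Depth at a base is the number of aligned segments overlapping it (both
mates, both split segments; duplicates are not removed, and all aligned
segment bases are counted). The summary reports mean depth = aligned bases
/ genome length and breadth = fraction of bases at or above each threshold
(default 4x). The provirus contig is excluded from the genome denominator
by default: the metrics describe the host genome, not the vector.

### Hypermutation

Each clone is globally aligned to the amplicon reference
(Needleman–Wunsch/Gotoh; match +1, mismatch −1, first gap base −4, each
further gap base −1; ties prefer the diagonal, then the gap consuming the
clone — fully deterministic). Substitution columns are tallied into a 4×4
spectrum; gap and N columns are excluded from the substitution count, with
gaps reported separately, since whether published mutation counts include
indels is typically unstated and RT-PCR/Sanger indels are a different error
process. The plus-strand G→A count, its fraction, and the dinucleotide
context of each G→A are reported; per-mouse summaries give the mean and
sample SD (n−1) of clone substitution counts.

## The synthetic-data generator

The generator's defaults are the study conditions the package is validated
under, and they are deliberately fixed rather than tuned:

| parameter | default | rationale |
|---|---|---|
| host genome | 2 placed contigs of 495 kb + 1 unplaced 10 kb scaffold (1 Mb) | smallest genome that exercises placed/unplaced logic at realistic depth |
| provirus | 8 kb, 600 bp terminal UTRs | MLV-scale provirus and LTR-scale UTRs |
| insertions | 1 germline heterozygous + 1 somatic at cell fraction 0.1 | the two-event situation the caller must distinguish |
| TSD | 4 bp | typical for MLV-family integrases; not stated by sources, configurable |
| reads | 2 × 150 bp, fragments N(400, 60) truncated at 150 | short-insert Illumina-style library |
| depth | 30x | matches the scale of a production WGS run |
| base errors | 1% substitutions | pessimistic Illumina error rate; stresses the mismatch caps |
| qualities | Phred 37 → floor 22 linear decay + N(0, 3) jitter, clipped to [2, 41] | produces nontrivial 3' trimming without modelling a real instrument |
| clones | 5 mice × 4–8 clones, 549 nt amplicon, Poisson(rate × length) substitutions, 80% forced plus-strand G→A | Sanger clone sets of a deaminase-attacked amplicon |

Haplotypes are built per contig (contigs are independent molecules):
a heterozygous germline insertion makes its contig a 50/50 carrier/reference
mixture, a homozygous one carrier-only, and a somatic insertion adds a
carrier variant sampled with probability equal to its cell fraction.
Fragment sources are chosen proportional to variant probability × variant
length, and the pair count follows depth × mean genome length / (2 ×
read length). The germline zygosity of a single-copy transgenic line can be
either; simulations default to heterozygous, the harder recovery problem.

Mate 1 copies the fragment head; mate 2 is the reverse complement of the
fragment tail. Every mate is recorded in a truth table (source variant,
0-based half-open coordinates, strand), and insertions in a truth BED, so
recovery is checkable without re-deriving anything.

What the generator does **not** emulate: indels and structural variants
beyond the provirus insertion, instrument-specific error and quality
profiles, diploid SNP backgrounds, GC bias, PCR duplicates, and adapter
read-through. Passing tests therefore demonstrate correctness of the
algorithms under a clean substitution-only error model — not robustness to
every artifact of real libraries.

## Numerical choices

* All internal coordinates are 0-based half-open; conversion to 1-based
  happens only at I/O boundaries (SAM POS, report TSV).
* The master seed fans out to per-component substreams (reference, reads,
  clones), so generating one artifact never shifts another's output.
* Seeding probes every third k-mer start plus the final one, which
  guarantees at least one seed in any error-free flank of `min_seg` ≥ 25 bp.
* k-mers with more than 32 genomic hits are skipped as repetitive; at most
  12 candidate diagonals are evaluated per read.
* Splits need a total score of at least 40 — roughly a clean 21-mer on each
  side — to suppress spurious two-segment placements of unmappable reads.
* Degenerate inputs: empty reads trim to empty; an empty split set clusters
  to an empty call table; a reference without a provirus contig is an error
  for trans-split extraction; zero-rate clone simulation returns exact
  copies.

## Validation scales

The test suite and the acceptance script validate against: 20 seeded
replicates of the full default simulation (1 Mb, 30x) for insertion
recovery; a constructed 31-split evidence set for the filter arithmetic;
1,000 random quality strings against an exhaustive trimming oracle;
brute-force score equivalence of the aligner on a 43 kb reference;
brute-force per-base counting for coverage; an independent dynamic-program
for alignment scores up to 30 nt; and 5 mice × 5 clones at a rate of
7.3 substitutions per 549 nt for the hypermutation recovery. These sizes
are the package's chosen validation conditions; all are generated in code
at run time.

## Limitations

* Ungapped split segments: indel-containing junction reads would be missed.
* Exact-match adapter clipping only.
* Split reads only — discordant read *pairs* are deliberately not used as
  evidence, and no assembly-based breakpoint refinement is attempted.
* The uniqueness margin is a scoring heuristic, not a mapping-quality
  posterior.
* Calls are not genotyped; somatic/germline interpretation is left to the
  analyst.
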