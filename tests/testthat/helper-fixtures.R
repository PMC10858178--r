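# Shared fixtures: scaled-down simulation configs and constructed chimeric
# reads with known junctions. All randomness is seeded per use.

# Small genome for fast end-to-end tests (~100 kb).
small_sim_config <- function(seed = 11L, depth = 20, ...) {
  sim_config(seed = seed,
             host_contigs = c(chr1 = 40000L, chr2 = 30000L),
             unplaced_contigs = c(scaffold_un1 = 6000L),
             provirus_len = 3000L, utr_len = 300L,
             depth = depth,
             events = list(
               insertion_event("chr1", 20000L, "+", 4L, "germline_het"),
               insertion_event("chr2", 15000L, "+", 4L, "somatic",
                               cell_fraction = 0.2)),
             ...)
}

# A chimeric read: `flank_a` bases of a host contig immediately before the
# junction position joined to the head (orientation +) of the provirus.
# Returns the read plus the constructed segment coordinates.
make_chimera <- function(refset, host_contig, host_break, flank_a, flank_b,
                         pv_from = c("start", "end")) {
  pv_from <- match.arg(pv_from)
  host <- refset$seqs[[host_contig]]
  pv <- refset$seqs[[refset$provirus_name]]
  prefix <- substr(host, host_break - flank_a + 1, host_break)
  suffix <- if (pv_from == "start") substr(pv, 1, flank_b)
  else substr(pv, nchar(pv) - flank_b + 1, nchar(pv))
  list(read = paste0(prefix, suffix),
       junction = flank_a,
       host_interval = c(host_break - flank_a, host_break),
       pv_interval = if (pv_from == "start") c(0L, flank_b)
       else c(nchar(pv) - flank_b, nchar(pv)))
}

# Leftmost-junction normalization of a constructed junction: extend while
# the next read base equals the continuation of the host (plus-strand)
# segment, mirroring the aligner's microhomology convention.
expected_junction <- function(read, refset, host_contig, host_break,
                              flank_a) {
  host <- refset$seqs[[host_contig]]
  j <- flank_a
  while (j < nchar(read) &&
         host_break + (j - flank_a) < nchar(host) &&
         substr(read, j + 1, j + 1) ==
         substr(host, host_break + (j - flank_a) + 1,
                host_break + (j - flank_a) + 1))
    j <- j + 1
  j
}

# A minimal trans-splits data.frame row, for call-layer tests that do not
# need real alignments.
ts_row <- function(host_contig, breakpoint, covers_utr = TRUE,
                   host_placed = TRUE, read_id = NULL) {
  data.frame(read_id = read_id %||% sprintf("r_%s_%d", host_contig,
                                            breakpoint),
             host_contig = host_contig, host_start = breakpoint - 50L,
             host_end = breakpoint + 1L, host_strand = "+",
             host_side = "a", host_breakpoint = as.integer(breakpoint),
             pv_start = if (covers_utr) 0L else 1000L,
             pv_end = if (covers_utr) 90L else 1090L,
             pv_strand = "+", covers_utr = covers_utr,
             host_placed = host_placed, unique = TRUE,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

with_seed_test <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Translate a truth-table coordinate on a carrier haplotype back to host
# reference coordinates; returns NA for positions inside the provirus or
# spanning a junction.
carrier_to_ref <- function(start, end, ins_pos, tsd, pv_len) {
  if (end <= ins_pos + tsd) return(c(start, end))
  if (start >= ins_pos + tsd + pv_len)
    return(c(start - tsd - pv_len, end - tsd - pv_len))
  c(NA_integer_, NA_integer_)
}
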