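# k-mer index and split-read alignment.

test_that("k-mer lookup enumerates exact forward-strand positions", {
  refset <- reference_set(c(g = "ACGTACGTACGTACGTACGTACGT"), placed = TRUE)
  idx <- build_index(refset, k = 4)
  hits <- kmer_lookup(idx, "ACGT")
  expect_equal(hits$pos, seq(0, 20, by = 4))
  expect_equal(unique(hits$contig), "g")
  expect_equal(nrow(kmer_lookup(idx, "AAAA")), 0)
  # rebuilding from the same input gives identical lookups
  idx2 <- build_index(refset, k = 4)
  expect_identical(kmer_lookup(idx2, "CGTA"), kmer_lookup(idx, "CGTA"))
  expect_error(build_index(refset, k = 30), "shortest contig")
})

ref_for_align <- function(seed = 77, host_len = 20000, pv_len = 3000) {
  with_seed_test(seed, {
    reference_set(
      c(chr1 = random_dna_test(host_len), provirus = random_dna_test(pv_len)),
      placed = c(TRUE, TRUE), provirus_name = "provirus",
      utr5 = c(0L, 300L), utr3 = c(pv_len - 300L, pv_len))
  })
}

test_that("verbatim reads align full at their origin and are unique", {
  refset <- ref_for_align()
  idx <- build_index(refset)
  read <- substr(refset$seqs[["chr1"]], 10001, 10150)
  a <- align_read(read, idx)
  expect_equal(a$type, "full")
  expect_equal(a$contig_a, "chr1")
  expect_equal(a$ref_start_a, 10000)
  expect_equal(a$ref_end_a, 10150)
  expect_equal(a$mismatches_a, 0)
  expect_equal(a$strand_a, "+")
  expect_true(a$unique)
  # reverse complement aligns to the same locus on the minus strand
  am <- align_read(revcomp(read), idx)
  expect_equal(am$type, "full")
  expect_equal(am$ref_start_a, 10000)
  expect_equal(am$strand_a, "-")
  # a random read finds no home in a small genome
  ar <- align_read(with_seed_test(123, random_dna_test(150)), idx)
  expect_equal(ar$type, "unmapped")
})

test_that("constructed chimeras are reported as splits at their junction", {
  refset <- ref_for_align()
  idx <- build_index(refset)
  ch <- make_chimera(refset, "chr1", 10000, flank_a = 60, flank_b = 90)
  a <- align_read(ch$read, idx)
  expect_equal(a$type, "split")
  expect_equal(a$contig_a, "chr1")
  expect_equal(a$contig_b, "provirus")
  jexp <- expected_junction(ch$read, refset, "chr1", 10000, 60)
  expect_equal(a$junction_offset, jexp)
  expect_equal(a$ref_end_a, 10000 + (jexp - 60))
  expect_equal(a$ref_start_b - (jexp - 60), 0)
  expect_true(a$unique)
  # strand symmetry: the reverse complement mirrors segments and strands
  ar <- align_read(revcomp(ch$read), idx)
  expect_equal(ar$type, "split")
  expect_equal(ar$contig_a, "provirus")
  expect_equal(ar$contig_b, "chr1")
  expect_equal(ar$strand_a, "-")
  expect_equal(ar$strand_b, "-")
  # the mirrored junction cannot absorb homology (the provirus segment ends
  # at contig coordinate 0), so the host segment ends at the constructed
  # breakpoint exactly
  expect_equal(ar$junction_offset, 90)
  expect_equal(ar$ref_start_b, 10000 - 60)
  expect_equal(ar$ref_end_b, 10000)
})

test_that("junction microhomology is absorbed by the first segment", {
  # craft a 3-base homology: the provirus head repeats the host bases
  # immediately after the junction
  with_seed_test(5150, {
    host <- random_dna_test(8000)
    pv <- paste0(substr(host, 4001, 4003), random_dna_test(2000))
  })
  refset <- reference_set(c(chr1 = host, provirus = pv),
                          placed = c(TRUE, TRUE), provirus_name = "provirus",
                          utr5 = c(0L, 200L),
                          utr3 = c(nchar(pv) - 200L, nchar(pv)))
  idx <- build_index(refset)
  read <- paste0(substr(host, 3951, 4000), substr(pv, 1, 70))
  a <- align_read(read, idx)
  expect_equal(a$type, "split")
  # bases 51..53 of the read match both loci; the convention assigns them
  # to the first (host) segment
  expect_equal(a$junction_offset, 53)
  expect_equal(a$ref_end_a, 4003)
  expect_equal(a$ref_start_b, 3)
  # resolve_microhomology reproduces the same normalization from an
  # unnormalized split
  b <- a
  b$junction_offset <- 50L
  b$read_end_a <- 50L
  b$ref_end_a <- 4000L
  b$read_start_b <- 50L
  b$ref_start_b <- 0L
  expect_equal(resolve_microhomology(b, read, refset)$junction_offset, 53)
  # no homology: a junction whose continuation mismatches stays put
  ch <- make_chimera(refset, "chr1", 2000, 60, 60)
  a2 <- align_read(ch$read, idx)
  expect_equal(resolve_microhomology(a2, ch$read, refset)$junction_offset,
               a2$junction_offset)
})

test_that("reported scores match brute-force best placements", {
  refset <- with_seed_test(88, reference_set(
    c(chr1 = random_dna_test(30000), provirus = random_dna_test(5000)),
    placed = c(TRUE, TRUE), provirus_name = "provirus",
    utr5 = c(0L, 300L), utr3 = c(4700L, 5000L)))
  idx <- build_index(refset)
  params <- align_params()
  with_seed_test(99, {
    cases <- list()
    for (i in 1:6) { # error-free full reads
      p <- sample(1000:28000, 1)
      cases[[length(cases) + 1]] <- substr(refset$seqs[["chr1"]], p, p + 149)
    }
    for (fl in c(30, 60, 110)) { # error-free chimeras
      ch <- make_chimera(refset, "chr1", sample(5000:20000, 1), fl, 150 - fl)
      cases[[length(cases) + 1]] <- ch$read
    }
  })
  for (read in cases) {
    got <- align_read(read, idx, params)
    expect_true(got$type %in% c("full", "split"))
    oracle <- brute_align_score(read, refset, params$min_seg,
                                params$max_mismatch_rate,
                                params$split_penalty)
    expect_equal(got$score, oracle)
  }
})

test_that("SAM output encodes splits as supplementary records and round-trips", {
  refset <- ref_for_align()
  idx <- build_index(refset)
  full <- substr(refset$seqs[["chr1"]], 5001, 5150)
  ch <- make_chimera(refset, "chr1", 12000, 70, 80)
  reads <- setNames(c(full, ch$read), c("rfull", "rsplit"))
  aln <- align_reads(reads, idx)
  d <- withr::local_tempdir()
  sam <- file.path(d, "out.sam")
  write_sam(aln, reads, refset, sam)
  lines <- readLines(sam)
  hdr <- grep("^@", lines, value = TRUE)
  expect_true(any(grepl("SN:chr1\tLN:20000", hdr)))
  rec <- strsplit(grep("^@", lines, value = TRUE, invert = TRUE), "\t")
  expect_equal(length(rec), 3) # one full + two split segments
  flags <- vapply(rec, function(x) as.integer(x[2]), integer(1))
  expect_equal(sum(bitwAnd(flags, 2048L) > 0), 1)
  # round trip: POS is 1-based ref_start of each segment
  byname <- split(rec, vapply(rec, `[`, character(1), 1))
  expect_equal(as.integer(byname$rfull[[1]][4]), aln$ref_start_a[1] + 1L)
  split_pos <- sort(vapply(byname$rsplit, function(x) as.integer(x[4]),
                           integer(1)))
  expect_equal(split_pos,
               sort(c(aln$ref_start_a[2], aln$ref_start_b[2]) + 1L))
  # SA tags cross-reference the partner segment
  expect_true(all(vapply(byname$rsplit, function(x)
    any(grepl("^SA:Z:", x)), logical(1))))
})
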