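# Quality trimming and pair filtering.

test_that("quality_trim matches exhaustive suffix-sum minimization", {
  # frozen worked example: suffix sums for cutoff 20 are minimised by
  # cutting after the first two bases
  tr <- quality_trim("ACGT", c(40, 40, 2, 2), 20)
  expect_equal(nchar(tr$seq), 2)
  expect_equal(tr$seq, "AC")
  expect_equal(tr$quals, c(40, 40))
  # high-quality reads are untouched; empty reads pass through
  expect_equal(quality_trim("ACGTACGT", rep(40, 8), 20)$seq, "ACGTACGT")
  expect_equal(quality_trim("", integer(0), 20)$seq, "")
  expect_error(quality_trim("ACGT", c(40, 40), 20), "length")
  # oracle equivalence over random quality strings
  set.seed(101)
  for (i in 1:1000) {
    L <- sample(1:60, 1)
    q <- sample(2:41, L, replace = TRUE)
    cutoff <- sample(c(5, 20, 30), 1)
    seq <- random_dna_test(L)
    got <- nchar(quality_trim(seq, q, cutoff)$seq)
    expect_identical(got, as.integer(trim_oracle(q, cutoff)),
                     label = sprintf("case %d (L=%d cutoff=%d)", i, L,
                                     cutoff))
  }
})

test_that("trimming is idempotent and monotone in the cutoff", {
  set.seed(202)
  for (i in 1:200) {
    L <- sample(5:80, 1)
    q <- sample(2:41, L, replace = TRUE)
    seq <- random_dna_test(L)
    t1 <- quality_trim(seq, q, 20)
    t2 <- quality_trim(t1$seq, t1$quals, 20)
    expect_identical(t2$seq, t1$seq)
    # raising the cutoff can only shorten the kept prefix
    lens <- vapply(c(5, 15, 25, 35),
                   function(cf) nchar(quality_trim(seq, q, cf)$seq),
                   numeric(1))
    expect_true(all(diff(lens) <= 0))
  }
})

test_that("pairs are discarded iff a mate is shorter than the minimum", {
  expect_false(filter_pair(strrep("A", 25), strrep("A", 19), 20))
  expect_true(filter_pair(strrep("A", 20), strrep("A", 20), 20))
  expect_false(filter_pair("", strrep("A", 150), 20))
})

test_that("trim_fastq applies adapter clipping, trimming and the filter", {
  good <- strrep("I", 30) # Phred 40
  reads <- data.frame(
    id = c("p1", "p2", "p3"),
    seq1 = c(strrep("ACGTA", 6), strrep("ACGTA", 6), strrep("ACGTA", 6)),
    qual1 = c(good, good, good),
    seq2 = c(strrep("TTACG", 6), strrep("TTACG", 6), strrep("TTACG", 6)),
    qual2 = c(good, strrep("#", 30), good), # '#' = Phred 2
    stringsAsFactors = FALSE)
  out <- trim_fastq(reads, trim_config(20, 20))
  # the all-quality-2 mate is emptied by trimming, so its pair is discarded
  expect_equal(out$reads$id, c("p1", "p3"))
  st <- out$stats
  expect_equal(st$pairs_in, 3)
  expect_equal(st$pairs_kept + st$pairs_discarded, st$pairs_in)
  expect_lte(st$bases_kept, st$bases_in)
  expect_equal(st$bases_in, 6 * 30)
  # adapter: exact-match clipping truncates at the adapter start
  adp <- "AACCGGTT"
  reads2 <- data.frame(id = "a1",
                       seq1 = paste0(strrep("ACGTA", 5), adp, "AC"),
                       qual1 = strrep("I", 35),
                       seq2 = strrep("TGCAT", 7),
                       qual2 = strrep("I", 35),
                       stringsAsFactors = FALSE)
  out2 <- trim_fastq(reads2, trim_config(20, 20, adapter = adp))
  expect_equal(out2$reads$seq1, strrep("ACGTA", 5))
  expect_equal(nchar(out2$reads$qual1), 25)
})

test_that("FASTQ round trip through files preserves reads and stats", {
  cfg <- small_sim_config(seed = 13)
  refset <- build_reference(cfg)
  sim <- simulate_reads(refset$seqs["chr1"], 1, cfg, n_pairs = 120)
  d <- withr::local_tempdir()
  write_fastq(paste0(sim$reads$id, "/1"), sim$reads$seq1, sim$reads$qual1,
              file.path(d, "r1.fastq"))
  write_fastq(paste0(sim$reads$id, "/2"), sim$reads$seq2, sim$reads$qual2,
              file.path(d, "r2.fastq"))
  st <- trim_fastq_files(file.path(d, "r1.fastq"), file.path(d, "r2.fastq"),
                         file.path(d, "t1.fastq"), file.path(d, "t2.fastq"),
                         trim_config(), file.path(d, "stats.json"))
  expect_equal(st$pairs_in, 120)
  expect_equal(st$pairs_kept + st$pairs_discarded, 120)
  t1 <- read_fastq(file.path(d, "t1.fastq"))
  expect_equal(nrow(t1), st$pairs_kept)
  js <- jsonlite::read_json(file.path(d, "stats.json"))
  expect_equal(js$pairs_in, 120)
})
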