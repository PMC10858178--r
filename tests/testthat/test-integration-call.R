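# Trans-split extraction, clustering and the discard rules.

call_refset <- function() {
  with_seed_test(404, reference_set(
    c(chr1 = random_dna_test(25000), chr2 = random_dna_test(15000),
      scaffold_un1 = random_dna_test(5000), provirus = random_dna_test(3000)),
    placed = c(TRUE, TRUE, FALSE, TRUE), provirus_name = "provirus",
    utr5 = c(0L, 300L), utr3 = c(2700L, 3000L)))
}

test_that("extraction keeps only unique host x provirus chimeras", {
  refset <- call_refset()
  idx <- build_index(refset)
  reads <- c(
    hostpv = make_chimera(refset, "chr1", 9000, 60, 90)$read,
    full = substr(refset$seqs[["chr2"]], 2001, 2150))
  aln <- align_reads(reads, idx)
  splits <- extract_trans_splits(aln, refset)
  expect_equal(nrow(splits), 1)
  expect_equal(splits$host_contig, "chr1")
  expect_equal(splits$pv_start, 0)
  expect_true(splits$covers_utr)
  expect_true(splits$host_placed)
  # the host breakpoint is the last host base before the provirus
  jexp <- expected_junction(reads[["hostpv"]], refset, "chr1", 9000, 60)
  expect_equal(splits$host_breakpoint, 9000 + (jexp - 60) - 1)
  # splits flagged non-unique are dropped under require_unique
  aln2 <- aln
  aln2$unique <- FALSE
  expect_equal(nrow(extract_trans_splits(aln2, refset)), 0)
  expect_equal(nrow(extract_trans_splits(
    aln2, refset, call_params(require_unique = FALSE))), 1)
  # a reference set without a provirus contig is an error
  nopv <- reference_set(c(chr1 = refset$seqs[["chr1"]]), placed = TRUE)
  expect_error(extract_trans_splits(aln, nopv), "provirus")
})

test_that("a host-provirus split with both segments on host is excluded", {
  refset <- call_refset()
  idx <- build_index(refset)
  # chimera joining two host loci: a split, but not a trans split
  read <- paste0(substr(refset$seqs[["chr1"]], 5001, 5070),
                 substr(refset$seqs[["chr2"]], 8001, 8080))
  aln <- align_read(read, idx)
  expect_equal(aln$type, "split")
  expect_equal(nrow(extract_trans_splits(aln, refset)), 0)
})

median_low_test <- function(x) sort(x)[(length(x) + 1) %/% 2]

test_that("single-linkage clustering merges within the window", {
  # 19 splits inside a 105-bp window collapse to one call of support 19
  bps <- as.integer(seq(4666860, 4666964, length.out = 19))
  splits <- do.call(rbind, lapply(seq_along(bps), function(i)
    ts_row("chr19", bps[i], read_id = sprintf("r%02d", i))))
  calls <- cluster_splits(splits, call_params(cluster_window = 300))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$support, 19)
  expect_equal(calls$span_start, 4666860)
  expect_equal(calls$span_end, 4666964)
  expect_equal(calls$breakpoint, median_low_test(bps))
  # empty input, empty output
  expect_equal(nrow(cluster_splits(splits[0, ])), 0)
  # two splits 10 kb apart stay separate calls of support 1
  far <- rbind(ts_row("chr1", 1000), ts_row("chr1", 11000))
  calls2 <- cluster_splits(far, call_params(cluster_window = 300))
  expect_equal(nrow(calls2), 2)
  expect_equal(calls2$support, c(1, 1))
  expect_true(all(calls2$singular))
})

test_that("discard rules match an exhaustive rule-by-rule oracle", {
  # directed cases first
  single_no_utr <- filter_calls(cluster_splits(
    ts_row("chr1", 500, covers_utr = FALSE)))
  expect_equal(single_no_utr$status, "discarded_no_utr")
  single_utr <- filter_calls(cluster_splits(ts_row("chr1", 500)))
  expect_equal(single_utr$status, "pass")
  unplaced <- filter_calls(cluster_splits(
    rbind(ts_row("scaffold_un1", 500, host_placed = FALSE),
          ts_row("scaffold_un1", 520, host_placed = FALSE,
                 read_id = "r2"))))
  expect_equal(unplaced$status, "discarded_unplaced")
  # property: random split sets agree with the oracle
  set.seed(777)
  for (rep in 1:20) {
    n <- sample(1:200, 1)
    splits <- do.call(rbind, lapply(seq_len(n), function(i) {
      contig <- sample(c("chr1", "chr2", "scaffold_un1"), 1)
      ts_row(contig, sample(1:50000, 1),
             covers_utr = runif(1) < 0.5,
             host_placed = contig != "scaffold_un1",
             read_id = sprintf("r%03d", i))
    }))
    calls <- filter_calls(cluster_splits(splits))
    oracle <- filter_oracle(splits)
    expect_equal(sum(calls$support), n) # conservation
    got <- calls[order(calls$host_contig, calls$breakpoint),
                 c("host_contig", "support", "status")]
    want <- oracle[order(oracle$host_contig), ]
    expect_equal(got$status, want$status)
    expect_equal(got$support, want$n)
  }
})

test_that("reports include BED/TSV/JSON and truth comparison", {
  refset <- call_refset()
  splits <- rbind(ts_row("chr1", 9000), ts_row("chr1", 9003, read_id = "rb"),
                  ts_row("chr2", 4000, covers_utr = FALSE))
  calls <- filter_calls(cluster_splits(splits))
  d <- withr::local_tempdir()
  truth <- data.frame(contig = "chr1", start = 9001L, end = 9005L,
                      stringsAsFactors = FALSE)
  rep <- report_calls(calls, refset, d, truth)
  expect_equal(rep$summary$n_pass, 1)
  expect_equal(rep$summary$n_discarded_no_utr, 1)
  expect_equal(rep$summary$splits_in_passing_calls, 2)
  expect_true(rep$summary$truth_comparison[[1]]$detected)
  expect_lte(rep$summary$truth_comparison[[1]]$breakpoint_error, 5)
  bed <- read.table(rep$bed, sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(bed), 1) # only the passing call
  tsv <- read.table(rep$tsv, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  expect_equal(nrow(tsv), 2) # discarded calls stay auditable
  expect_setequal(tsv$status, c("pass", "discarded_no_utr"))
  # breakpoints in the TSV are 1-based
  expect_equal(tsv$breakpoint[tsv$status == "pass"], 9000 + 1)
  # zero passing calls still writes an empty BED and a summary
  none <- filter_calls(cluster_splits(
    ts_row("chr2", 100, covers_utr = FALSE)))
  rep2 <- report_calls(none, refset, file.path(d, "none"))
  expect_equal(rep2$summary$n_pass, 0)
  expect_true(file.exists(rep2$bed))
  expect_equal(file.size(rep2$bed), 0)
})
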