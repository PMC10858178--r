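# Synthetic-data generator: references, insertion haplotypes, reads, clones.

test_that("build_reference is deterministic and bookkeeping is exact", {
  cfg <- sim_config(seed = 3,
                    host_contigs = c(chrA = 5000L, chrB = 5000L),
                    unplaced_contigs = c(un1 = 1000L),
                    provirus_len = 2000L, utr_len = 300L)
  r1 <- build_reference(cfg)
  r2 <- build_reference(cfg)
  expect_identical(r1$seqs, r2$seqs)
  expect_equal(nrow(r1$info), 4)
  expect_equal(sum(r1$info$is_provirus), 1)
  expect_equal(sum(!r1$info$placed), 1)
  expect_equal(r1$info$length, c(5000L, 5000L, 1000L, 2000L))
  # UTR intervals derive from utr_len and provirus_len
  expect_equal(r1$annotation$utr5, c(0L, 300L))
  expect_equal(r1$annotation$utr3, c(1700L, 2000L))
  # a different seed changes the sequence
  expect_false(identical(build_reference(sim_config(seed = 4,
    host_contigs = c(chrA = 5000L, chrB = 5000L),
    unplaced_contigs = c(un1 = 1000L),
    provirus_len = 2000L, utr_len = 300L))$seqs[[1]], r1$seqs[[1]]))
  expect_error(sim_config(host_contigs = c(chrA = 0L)), "positive")
})

test_that("insert_provirus places the TSD on both sides of the provirus", {
  set.seed(42)
  host <- random_dna_test(1000)
  pv <- random_dna_test(500)
  ev <- insertion_event("h", 300L, "+", tsd_len = 4L)
  carrier <- insert_provirus(host, pv, ev)
  expect_equal(nchar(carrier), 1000 + 500 + 4)
  tsd <- substr(host, 301, 304)
  expect_equal(substr(carrier, 301, 304), tsd)
  expect_equal(substr(carrier, 301 + 4 + 500, 304 + 4 + 500), tsd)
  # full reconstruction: prefix + TSD + provirus + suffix
  expect_equal(carrier,
               paste0(substr(host, 1, 304), pv, substr(host, 301, 1000)))
  # tsd = 0 is a plain splice
  ev0 <- insertion_event("h", 300L, "+", tsd_len = 0L)
  expect_equal(insert_provirus(host, pv, ev0),
               paste0(substr(host, 1, 300), pv, substr(host, 301, 1000)))
  # minus orientation inserts the reverse complement
  evm <- insertion_event("h", 300L, "-", tsd_len = 2L)
  expect_equal(substr(insert_provirus(host, pv, evm), 303, 802),
               revcomp(pv))
  expect_error(insert_provirus(host, pv, insertion_event("h", 999L, "+", 4L)),
               "bounds")
})

test_that("error-free simulated reads are exact substrings of their source", {
  cfg <- small_sim_config(seed = 5, base_error_rate = 0)
  refset <- build_reference(cfg)
  haps <- list(seqs = setNames(refset$seqs[1:2], c("h1", "h2")),
               weights = c(0.5, 0.5))
  sim <- simulate_reads(haps$seqs, haps$weights, cfg, n_pairs = 200)
  expect_equal(nrow(sim$reads), 200)
  ok <- vapply(seq_len(200), function(i) {
    tr1 <- sim$truth[sim$truth$read_id == paste0(sim$reads$id[i], "/1"), ]
    tr2 <- sim$truth[sim$truth$read_id == paste0(sim$reads$id[i], "/2"), ]
    src <- haps$seqs[[tr1$haplotype]]
    identical(substr(src, tr1$start + 1, tr1$end), sim$reads$seq1[i]) &&
      identical(revcomp(substr(src, tr2$start + 1, tr2$end)),
                sim$reads$seq2[i])
  }, logical(1))
  expect_true(all(ok))
})

test_that("pair count follows the depth expectation and output is seeded", {
  cfg <- small_sim_config(seed = 9)
  set.seed(1) # simulate_reads must not depend on ambient RNG state
  hap <- setNames(paste(rep("ACGT", 25000), collapse = ""), "h")
  sim1 <- simulate_reads(hap, 1, cfg)
  # depth 20, genome 100 kb, 2 x 150 bp -> 20 * 1e5 / 300 pairs
  expect_equal(nrow(sim1$reads), round(20 * 1e5 / 300))
  set.seed(99)
  sim2 <- simulate_reads(hap, 1, cfg)
  expect_identical(sim1$reads, sim2$reads)
  # truth-table completeness: every mate id exactly once
  expect_equal(anyDuplicated(sim1$truth$read_id), 0)
  expect_setequal(sim1$truth$read_id,
                  c(paste0(sim1$reads$id, "/1"), paste0(sim1$reads$id, "/2")))
  # qualities stay within the Phred alphabet
  q <- utf8ToInt(paste(sim1$reads$qual1[1:50], collapse = "")) - 33
  expect_true(all(q >= 2 & q <= 41))
  expect_error(simulate_reads(hap, 1,
                              small_sim_config(seed = 1, depth = -1)),
               "positive")
})

test_that("whole-genome simulation writes consistent truth tables", {
  cfg <- small_sim_config(seed = 21)
  refset <- build_reference(cfg)
  sim <- simulate_wgs(refset, cfg)
  expect_equal(nrow(sim$truth), 2 * nrow(sim$reads))
  expect_equal(nrow(sim$truth_bed), 2)
  expect_setequal(sim$truth_bed$name, c("germline_het", "somatic"))
  expect_equal(sim$truth_bed$end - sim$truth_bed$start, c(4L, 4L))
  # haplotype weights: germline het mixes carrier and reference alleles
  # 50/50, with fragment sampling proportional to variant length
  haps <- sim$haplotypes
  w <- haps$weights
  germ <- grepl("germline", names(haps$seqs))
  lens <- nchar(haps$seqs)
  want <- 0.5 * lens[haps$contig == "chr1" & germ] /
    (0.5 * sum(lens[haps$contig == "chr1"]))
  expect_equal(unname(sum(w[haps$contig == "chr1" & germ]) /
                        sum(w[haps$contig == "chr1"])), unname(want),
               tolerance = 1e-9)
})

test_that("clone simulation honours rate zero and the G>A signature", {
  cfg <- small_sim_config(seed = 31, clone_mut_rate = 0)
  ref <- with_seed_test(7, random_dna_test(549))
  cl0 <- simulate_clones(ref, cfg)
  expect_true(all(cl0$clones == ref))
  expect_equal(nrow(cl0$truth), 0)
  cfg2 <- small_sim_config(seed = 31, clone_mut_rate = 7.3 / 549,
                           clone_ga_fraction = 1)
  cl1 <- simulate_clones(ref, cfg2)
  expect_gt(nrow(cl1$truth), 0)
  expect_true(all(cl1$truth$ref == "G" & cl1$truth$alt == "A"))
  # clone counts per mouse stay in the configured range
  counts <- table(sub("_c\\d+$", "", names(cl1$clones)))
  expect_true(all(counts >= 4 & counts <= 8))
  expect_equal(length(counts), cfg2$n_mice)
  # truth mutations reproduce the clone sequences exactly
  for (id in names(cl1$clones)[1:3]) {
    s <- strsplit(ref, "")[[1]]
    tr <- cl1$truth[cl1$truth$clone_id == id, ]
    s[tr$pos + 1] <- tr$alt
    expect_equal(paste(s, collapse = ""), cl1$clones[[id]])
  }
  expect_error(simulate_clones(ref, small_sim_config(clone_mut_rate = -1)),
               "non-negative")
})
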