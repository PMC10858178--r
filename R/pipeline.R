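# Pipeline orchestration: stage subcommands, config handling, manifest.

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @param sim a [sim_config()].
#' @param trim a [trim_config()].
#' @param align an [align_params()].
#' @param call a [call_params()].
#' @param coverage_thresholds depth thresholds for breadth.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir = "proviscan_out", seed = 1L,
                            sim = sim_config(seed = seed),
                            trim = trim_config(),
                            align = align_params(),
                            call = call_params(),
                            coverage_thresholds = 4L) {
  structure(list(outdir = outdir, seed = as.integer(seed), sim = sim,
                 trim = trim, align = align, call = call,
                 coverage_thresholds = coverage_thresholds),
            class = "pipeline_config")
}

log_msg <- function(...) message("[proviscan] ", sprintf(...))

#' Run pipeline stages
#'
#' Subcommands: `"simulate"` (write reference, reads and truth tables),
#' `"trim"`, `"align"`, `"call"`, `"coverage"`, `"mutations"` and
#' `"run-all"` (trim, align, call and coverage in sequence, plus a
#' truth-vs-called comparison when the simulation truth is present). All
#' stages read and write under `config$outdir`; `run-all` finishes by
#' writing a JSON manifest listing every artifact with its MD5 checksum and
#' the full parameter set. Partial outputs of a failed stage are removed.
#'
#' @param subcommand one of the stage names above.
#' @param config a [pipeline_config()].
#' @return list of artifact paths produced by the stage, invisibly.
#' @export
run_pipeline <- function(subcommand = c("run-all", "simulate", "trim",
                                        "align", "call", "coverage",
                                        "mutations"),
                         config = pipeline_config()) {
  subcommand <- match.arg(subcommand)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  made <- character(0)
  on_fail <- function(e) {
    unlink(made)
    stop("stage '", subcommand, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }
  p <- function(...) file.path(config$outdir, ...)
  tryCatch(switch(subcommand,
    "simulate" = {
      log_msg("simulate: seed %d", config$sim$seed)
      refset <- build_reference(config$sim)
      made <- c(p("reference.fasta"), p("reads_1.fastq"), p("reads_2.fastq"),
                p("read_truth.tsv"), p("insertions_truth.bed"),
                p("provirus_utr.bed"))
      write_fasta(refset$seqs, p("reference.fasta"))
      sim <- simulate_wgs(refset, config$sim)
      write_fastq(paste0(sim$reads$id, "/1"), sim$reads$seq1,
                  sim$reads$qual1, p("reads_1.fastq"))
      write_fastq(paste0(sim$reads$id, "/2"), sim$reads$seq2,
                  sim$reads$qual2, p("reads_2.fastq"))
      write_truth_tsv(sim$truth, p("read_truth.tsv"))
      write_bed(sim$truth_bed, p("insertions_truth.bed"))
      ann <- refset$annotation
      write_bed(data.frame(contig = config$sim$provirus_name,
                           start = c(ann$utr5[1], ann$utr3[1]),
                           end = c(ann$utr5[2], ann$utr3[2]),
                           name = c("utr5", "utr3"),
                           stringsAsFactors = FALSE),
                p("provirus_utr.bed"))
      contig_meta <- refset$info[, c("name", "placed", "is_provirus")]
      write.table(contig_meta, p("contigs.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      log_msg("simulate: %d pairs written", nrow(sim$reads))
      invisible(list(reference = p("reference.fasta"),
                     fastq1 = p("reads_1.fastq"), fastq2 = p("reads_2.fastq"),
                     truth = p("read_truth.tsv"),
                     truth_bed = p("insertions_truth.bed")))
    },
    "trim" = {
      made <- c(p("trimmed_1.fastq"), p("trimmed_2.fastq"),
                p("trim_stats.json"))
      log_msg("trim: cutoff %d, min length %d",
              config$trim$quality_cutoff, config$trim$min_len)
      st <- trim_fastq_files(p("reads_1.fastq"), p("reads_2.fastq"),
                             p("trimmed_1.fastq"), p("trimmed_2.fastq"),
                             config$trim, p("trim_stats.json"))
      log_msg("trim: %d/%d pairs kept", st$pairs_kept, st$pairs_in)
      invisible(list(fastq1 = p("trimmed_1.fastq"),
                     fastq2 = p("trimmed_2.fastq"),
                     stats = p("trim_stats.json")))
    },
    "align" = {
      made <- c(p("alignments.tsv"), p("splits.tsv"))
      refset <- load_reference_dir(config)
      log_msg("align: k %d, min segment %d", config$align$k,
              config$align$min_seg)
      idx <- build_index(refset, config$align$k)
      r1 <- read_fastq(p("trimmed_1.fastq"))
      r2 <- read_fastq(p("trimmed_2.fastq"))
      reads <- setNames(c(r1$seq, r2$seq), c(r1$id, r2$id))
      aln <- align_reads(reads, idx, config$align)
      write.table(aln, p("alignments.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_splits_tsv(aln, p("splits.tsv"))
      log_msg("align: %d reads, %d full, %d split, %d unmapped",
              nrow(aln), sum(aln$type == "full"), sum(aln$type == "split"),
              sum(aln$type == "unmapped"))
      invisible(list(alignments = p("alignments.tsv"),
                     splits = p("splits.tsv")))
    },
    "call" = {
      refset <- load_reference_dir(config)
      aln <- read.table(p("alignments.tsv"), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      splits <- extract_trans_splits(aln, refset, config$call)
      calls <- filter_calls(cluster_splits(splits, config$call))
      truth_bed <- if (file.exists(p("insertions_truth.bed")))
        read_bed(p("insertions_truth.bed")) else NULL
      rep <- report_calls(calls, refset, config$outdir, truth_bed)
      log_msg("call: %d calls, %d pass", rep$summary$n_calls,
              rep$summary$n_pass)
      invisible(rep[c("bed", "tsv", "json")])
    },
    "coverage" = {
      refset <- load_reference_dir(config)
      aln <- read.table(p("alignments.tsv"), header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
      prof <- depth_profile(aln, refset)
      summ <- coverage_summary(prof, refset, config$coverage_thresholds)
      out <- write_coverage(summ, config$outdir)
      log_msg("coverage: mean %.2fx", summ$mean_depth)
      invisible(out)
    },
    "mutations" = {
      log_msg("mutations: clone analysis")
      ref <- with_seed(derive_seed(config$sim$seed, "amplicon"),
                       random_dna(config$sim$amplicon_len))
      cl <- simulate_clones(ref, config$sim)
      write_fasta(c(amplicon_ref = ref, cl$clones), p("clones.fasta"))
      res <- analyze_clone_fasta(p("clones.fasta"), config$outdir)
      invisible(list(clones = p("clones.fasta"),
                     per_clone = p("clones.tsv"),
                     per_mouse = p("mice.tsv")))
    },
    "run-all" = {
      arts <- list()
      for (s in c("trim", "align", "call", "coverage"))
        arts[[s]] <- run_pipeline(s, config)
      manifest <- list(
        created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
        seed = config$seed,
        parameters = strip_classes(config),
        outputs = pipeline_checksums(config$outdir))
      write_json(manifest, p("manifest.json"))
      log_msg("run-all: manifest written")
      invisible(c(arts, list(manifest = p("manifest.json"))))
    }),
    error = on_fail)
}

# Reload the reference written by the simulate stage (or provided by the
# user in the same layout): reference.fasta + contigs.tsv + provirus UTR BED.
load_reference_dir <- function(config) {
  p <- function(...) file.path(config$outdir, ...)
  seqs <- read_fasta(p("reference.fasta"))
  meta <- read.table(p("contigs.tsv"), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  utr <- read_bed(p("provirus_utr.bed"))
  pv <- meta$name[meta$is_provirus]
  reference_set(seqs[meta$name], meta$placed, pv,
                utr5 = unlist(utr[utr$name == "utr5", c("start", "end")],
                              use.names = FALSE),
                utr3 = unlist(utr[utr$name == "utr3", c("start", "end")],
                              use.names = FALSE))
}

strip_classes <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), strip_classes))
  x
}

# MD5 checksums of every regular file in the output directory, excluding
# the manifest itself (stable across reruns with the same seed).
pipeline_checksums <- function(outdir) {
  fs <- sort(setdiff(list.files(outdir, recursive = TRUE), "manifest.json"))
  sums <- tools::md5sum(file.path(outdir, fs))
  mapply(function(f, s) list(file = f, md5 = unname(s)), fs, sums,
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Command-line entry point
#'
#' Parses `argv` of the form `<subcommand> [--outdir DIR] [--seed N]
#' [--quality-cutoff Q] [--min-length L] [--cluster-window W] [--k K]`,
#' builds the matching [pipeline_config()] and dispatches to
#' [run_pipeline()]. Installed as `inst/scripts/proviscan.R`.
#'
#' @param argv character vector of command-line arguments (defaults to
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (0 on success), invisibly.
#' @export
proviscan_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0 || argv[1] %in% c("-h", "--help")) {
    cat("usage: proviscan.R <simulate|trim|align|call|coverage|mutations|run-all> [options]\n")
    return(invisible(1L))
  }
  sub <- argv[1]
  opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
    optparse::make_option("--outdir", default = "proviscan_out"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--quality-cutoff", type = "integer",
                          default = 20L, dest = "quality_cutoff"),
    optparse::make_option("--min-length", type = "integer", default = 20L,
                          dest = "min_length"),
    optparse::make_option("--cluster-window", type = "integer",
                          default = 300L, dest = "cluster_window"),
    optparse::make_option("--k", type = "integer", default = 21L))),
    args = argv[-1])
  cfg <- pipeline_config(
    outdir = opts$outdir, seed = opts$seed,
    trim = trim_config(opts$quality_cutoff, opts$min_length),
    align = align_params(k = opts$k),
    call = call_params(cluster_window = opts$cluster_window))
  status <- tryCatch({ run_pipeline(sub, cfg); 0L },
                     error = function(e) {
                       message("error: ", conditionMessage(e))
                       1L
                     })
  invisible(status)
}
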