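# Synthetic reference construction: host contigs (placed chromosomes and
# unplaced scaffolds), the provirus contig with annotated terminal UTRs,
# and insertion haplotypes with target-site duplication (TSD).

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. Defaults describe
#' the study conditions the package is validated under: a 1 Mb host genome
#' (two placed chromosomes plus one unplaced scaffold), an 8 kb provirus
#' with 600 bp terminal UTRs, one heterozygous germline insertion and one
#' somatic insertion at cell fraction 0.1, 2 x 150 bp pairs at 30x with 1%
#' base-call error, and amplicon clone sets of 549 nt mutated at a
#' deaminase-dominated rate.
#'
#' @param seed master RNG seed; each generator component derives its own
#'   substream from it, so outputs do not depend on call order.
#' @param host_contigs named integer vector of placed-chromosome lengths.
#' @param unplaced_contigs named integer vector of unplaced-scaffold lengths.
#' @param provirus_len provirus length (bp).
#' @param utr_len length of each terminal UTR (bp); the 5' UTR is
#'   `[0, utr_len)` and the 3' UTR `[provirus_len - utr_len, provirus_len)`.
#' @param provirus_name contig name given to the provirus.
#' @param read_len read length (bp).
#' @param frag_mean,frag_sd fragment-length normal distribution (bp),
#'   truncated below at `read_len`.
#' @param depth target mean sequencing depth (x).
#' @param base_error_rate per-base substitution error probability.
#' @param q_start,q_floor,q_jitter_sd quality model: Phred starts at
#'   `q_start`, decays linearly to `q_floor` at the 3' end, with Gaussian
#'   jitter of this SD, clipped to `[2, 41]`.
#' @param tsd_len target-site duplication length (bp).
#' @param events list of [insertion_event()] ground-truth insertions.
#' @param n_mice number of mice for the amplicon clone simulation.
#' @param clones_per_mouse integer range `c(min, max)` of clones per mouse.
#' @param amplicon_len amplicon reference length (nt).
#' @param clone_mut_rate per-base substitution rate of the clone simulation;
#'   the per-clone count is Poisson(rate x length).
#' @param clone_ga_fraction fraction of clone mutations forced to be
#'   plus-strand G>A (the deaminase signature); the rest are uniform
#'   substitutions.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       host_contigs = c(chr1 = 495000L, chr2 = 495000L),
                       unplaced_contigs = c(scaffold_un1 = 10000L),
                       provirus_len = 8000L,
                       utr_len = 600L,
                       provirus_name = "provirus",
                       read_len = 150L,
                       frag_mean = 400,
                       frag_sd = 60,
                       depth = 30,
                       base_error_rate = 0.01,
                       q_start = 37,
                       q_floor = 22,
                       q_jitter_sd = 3,
                       tsd_len = 4L,
                       events = NULL,
                       n_mice = 5L,
                       clones_per_mouse = c(4L, 8L),
                       amplicon_len = 549L,
                       clone_mut_rate = 7.3 / 549,
                       clone_ga_fraction = 0.8) {
  if (is.null(events)) {
    events <- list(
      insertion_event("chr1", 250000L, "+", tsd_len, "germline_het"),
      insertion_event("chr2", 300000L, "+", tsd_len, "somatic",
                      cell_fraction = 0.1))
  }
  cfg <- list(seed = as.integer(seed), host_contigs = host_contigs,
              unplaced_contigs = unplaced_contigs,
              provirus_len = as.integer(provirus_len),
              utr_len = as.integer(utr_len),
              provirus_name = provirus_name,
              read_len = as.integer(read_len),
              frag_mean = frag_mean, frag_sd = frag_sd, depth = depth,
              base_error_rate = base_error_rate,
              q_start = q_start, q_floor = q_floor,
              q_jitter_sd = q_jitter_sd,
              tsd_len = as.integer(tsd_len), events = events,
              n_mice = as.integer(n_mice),
              clones_per_mouse = as.integer(clones_per_mouse),
              amplicon_len = as.integer(amplicon_len),
              clone_mut_rate = clone_mut_rate,
              clone_ga_fraction = clone_ga_fraction)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  lens <- c(cfg$host_contigs, cfg$unplaced_contigs, cfg$provirus_len,
            cfg$utr_len, cfg$read_len, cfg$amplicon_len)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$base_error_rate < 0 || cfg$base_error_rate >= 1)
    stop("base_error_rate must be in [0, 1)")
  if (cfg$clone_mut_rate < 0) stop("clone_mut_rate must be non-negative")
  if (2 * cfg$utr_len > cfg$provirus_len)
    stop("UTRs must not overlap: 2 * utr_len must not exceed provirus_len")
  if (is.null(names(cfg$host_contigs)))
    stop("host_contigs must be named")
  invisible(cfg)
}

#' Ground-truth insertion event
#'
#' @param host_contig name of the host contig receiving the insertion.
#' @param position 0-based bp; the provirus is inserted before this base.
#' @param orientation `"+"` or `"-"` (minus inserts the reverse complement).
#' @param tsd_len target-site duplication length (bp, >= 0).
#' @param mode `"germline_het"`, `"germline_hom"` or `"somatic"`.
#' @param cell_fraction fraction of cells carrying a somatic insertion (in
#'   (0, 1]); forced to 1 for germline modes, where allele dosage is encoded
#'   by the mode itself.
#' @return object of class `insertion_event`.
#' @export
insertion_event <- function(host_contig, position, orientation = "+",
                            tsd_len = 4L, mode = "germline_het",
                            cell_fraction = 1) {
  mode <- match.arg(mode, c("germline_het", "germline_hom", "somatic"))
  if (!orientation %in% c("+", "-")) stop("orientation must be '+' or '-'")
  if (position < 0) stop("position must be non-negative")
  if (tsd_len < 0) stop("tsd_len must be non-negative")
  if (mode != "somatic") cell_fraction <- 1
  if (cell_fraction <= 0 || cell_fraction > 1)
    stop("cell_fraction must be in (0, 1]")
  structure(list(host_contig = host_contig, position = as.integer(position),
                 orientation = orientation, tsd_len = as.integer(tsd_len),
                 mode = mode, cell_fraction = cell_fraction),
            class = "insertion_event")
}

#' Reference set constructor
#'
#' A reference set is the host assembly (placed chromosomes plus unplaced
#' scaffolds) together with at most one provirus contig whose terminal UTR
#' intervals are annotated.
#'
#' @param seqs named character vector of contig sequences.
#' @param placed logical vector (parallel to `seqs`): assembled chromosome
#'   (`TRUE`) or unplaced scaffold (`FALSE`).
#' @param provirus_name name of the provirus contig, or `NA` for none.
#' @param utr5,utr3 0-based half-open intervals `c(start, end)` on the
#'   provirus contig; `utr5` must start at 0 and `utr3` end at the provirus
#'   length.
#' @return object of class `ReferenceSet` with elements `seqs`, `info`
#'   (data.frame: name, length, placed, is_provirus) and `annotation`.
#' @export
reference_set <- function(seqs, placed, provirus_name = NA_character_,
                          utr5 = NULL, utr3 = NULL) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("contig names must be present and unique")
  if (any(nchar(seqs) == 0)) stop("contig sequences must be non-empty")
  if (length(placed) != length(seqs)) stop("placed must parallel seqs")
  is_pv <- names(seqs) == provirus_name
  if (!is.na(provirus_name)) {
    if (sum(is_pv) != 1)
      stop("provirus contig '", provirus_name, "' not found")
    plen <- nchar(seqs[[provirus_name]])
    if (is.null(utr5) || is.null(utr3))
      stop("provirus UTR intervals are required")
    if (utr5[1] != 0) stop("utr5 must start at 0")
    if (utr3[2] != plen) stop("utr3 must end at the provirus length")
    if (utr5[2] > utr3[1]) stop("UTR intervals must not overlap")
    if (diff(utr5) < 1 || diff(utr3) < 1) stop("UTRs must be >= 1 bp")
  } else {
    is_pv[] <- FALSE
  }
  info <- data.frame(name = names(seqs), length = nchar(seqs),
                     placed = placed, is_provirus = is_pv,
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(seqs = toupper(seqs), info = info,
                 annotation = list(utr5 = utr5, utr3 = utr3),
                 provirus_name = provirus_name),
            class = "ReferenceSet")
}

#' @export
print.ReferenceSet <- function(x, ...) {
  cat("ReferenceSet:", nrow(x$info), "contigs,",
      sum(x$info$length), "bp total\n")
  cat("  placed:", sum(x$info$placed & !x$info$is_provirus),
      " unplaced:", sum(!x$info$placed & !x$info$is_provirus),
      " provirus:", sum(x$info$is_provirus), "\n")
  if (!is.na(x$provirus_name))
    cat("  provirus '", x$provirus_name, "' UTR5 [",
        x$annotation$utr5[1], ",", x$annotation$utr5[2], ") UTR3 [",
        x$annotation$utr3[1], ",", x$annotation$utr3[2], ")\n", sep = "")
  invisible(x)
}

#' Build a synthetic reference set
#'
#' Draws uniform-random host contigs (placed and unplaced) and a provirus
#' contig, annotating the provirus terminal UTRs. Deterministic for a given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [reference_set()].
#' @export
build_reference <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "reference"), {
    host <- vapply(c(config$host_contigs, config$unplaced_contigs),
                   random_dna, character(1))
    pv <- setNames(random_dna(config$provirus_len), config$provirus_name)
    seqs <- c(host, pv)
    placed <- c(rep(TRUE, length(config$host_contigs)),
                rep(FALSE, length(config$unplaced_contigs)),
                TRUE)
    reference_set(seqs, placed, config$provirus_name,
                  utr5 = c(0L, config$utr_len),
                  utr3 = c(config$provirus_len - config$utr_len,
                           config$provirus_len))
  })
}

#' Insert a provirus into a host sequence with target-site duplication
#'
#' Returns the carrier haplotype: host prefix up to `position + tsd_len`,
#' then the provirus (reverse complement for orientation `-`), then the host
#' suffix from `position` on — so the `tsd_len` host bases at
#' `[position, position + tsd_len)` flank the provirus on both sides.
#'
#' @param host host contig sequence (character scalar).
#' @param provirus provirus sequence (character scalar).
#' @param event an [insertion_event()].
#' @return character scalar of length
#'   `nchar(host) + nchar(provirus) + tsd_len`.
#' @export
insert_provirus <- function(host, provirus, event) {
  p <- event$position
  t <- event$tsd_len
  hl <- nchar(host)
  if (p < 0 || p + t > hl)
    stop("insertion position (plus TSD) out of host bounds")
  pv <- if (event$orientation == "-") revcomp(provirus) else provirus
  paste0(substr(host, 1, p + t), pv, substr(host, p + 1, hl))
}

# Per-contig haplotype variants with sampling weights. Germline het contigs
# are a 50/50 mixture of reference and carrier alleles (hom: carrier only);
# a somatic insertion adds a carrier variant sampled with probability equal
# to its cell fraction. Contigs are molecules, so variants are built per
# contig, not per whole-genome haplotype.
build_haplotypes <- function(refset, events, config) {
  pv_name <- refset$provirus_name
  if (is.na(pv_name)) stop("reference set has no provirus contig")
  pv_seq <- refset$seqs[[pv_name]]
  host_info <- refset$info[!refset$info$is_provirus, ]
  seqs <- character(0)
  weights <- numeric(0)
  contig_of <- character(0)
  variant_of <- character(0)
  truth <- list()
  for (cn in host_info$name) {
    base <- refset$seqs[[cn]]
    evs <- Filter(function(e) e$host_contig == cn, events)
    if (length(evs) == 0) {
      seqs <- c(seqs, setNames(base, paste0(cn, "|ref")))
      weights <- c(weights, 1 * nchar(base))
      contig_of <- c(contig_of, cn)
      variant_of <- c(variant_of, "ref")
      next
    }
    if (length(evs) > 1)
      stop("at most one insertion event per contig is supported")
    e <- evs[[1]]
    carrier <- insert_provirus(base, pv_seq, e)
    w_carrier <- switch(e$mode,
                        germline_het = 0.5,
                        germline_hom = 1,
                        somatic = e$cell_fraction)
    truth[[length(truth) + 1]] <-
      data.frame(contig = cn, start = e$position,
                 end = e$position + e$tsd_len,
                 name = e$mode, score = e$cell_fraction,
                 strand = e$orientation, stringsAsFactors = FALSE)
    if (w_carrier < 1) {
      seqs <- c(seqs, setNames(base, paste0(cn, "|ref")))
      weights <- c(weights, (1 - w_carrier) * nchar(base))
      contig_of <- c(contig_of, cn)
      variant_of <- c(variant_of, "ref")
    }
    seqs <- c(seqs, setNames(carrier, paste0(cn, "|", e$mode)))
    weights <- c(weights, w_carrier * nchar(carrier))
    contig_of <- c(contig_of, cn)
    variant_of <- c(variant_of, e$mode)
  }
  genome_len <- sum(weights) # mean genome length across the variant mixture
  weights <- weights / sum(weights)
  truth_bed <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               name = character(0), score = numeric(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(seqs = seqs, weights = weights, contig = contig_of,
       variant = variant_of, truth_bed = truth_bed,
       genome_len = genome_len)
}
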