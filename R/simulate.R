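# Paired-end read simulation and amplicon clone simulation.

#' Simulate paired-end reads from weighted haplotype sequences
#'
#' Fragments are drawn from a normal length distribution (truncated below at
#' `read_len`), started uniformly within the sampled source sequence; mate 1
#' copies the fragment head and mate 2 is the reverse complement of the
#' fragment tail. Substitution errors occur per base at
#' `config$base_error_rate`; qualities decay linearly from `q_start` to
#' `q_floor` with Gaussian jitter. The expected pair count is
#' `depth * weighted_mean_genome_length / (2 * read_len)`.
#'
#' @param haplotypes named character vector of source sequences.
#' @param weights sampling weights, summing to 1.
#' @param config a [sim_config()]; `depth`, `read_len`, fragment and error
#'   parameters are taken from it.
#' @param n_pairs override the computed pair count (optional).
#' @param id_prefix prefix for read identifiers.
#' @return list with `reads` (data.frame: id, seq1, qual1, seq2, qual2) and
#'   `truth` (data.frame, one row per mate: read_id, haplotype, start, end,
#'   strand — 0-based half-open source coordinates).
#' @export
simulate_reads <- function(haplotypes, weights, config, n_pairs = NULL,
                           id_prefix = "sim") {
  if (length(haplotypes) == 0) stop("haplotypes must be non-empty")
  if (length(weights) != length(haplotypes))
    stop("weights must parallel haplotypes")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  if (config$depth <= 0) stop("depth must be positive")
  rl <- config$read_len
  if (is.null(n_pairs)) {
    # expected pair count: depth x (weighted mean genome length) / (2R)
    mean_len <- sum(weights * nchar(haplotypes))
    n_pairs <- as.integer(round(config$depth * mean_len / (2 * rl)))
  }
  sim <- with_seed(derive_seed(config$seed, "reads"), {
    cpp_simulate_pairs(unname(haplotypes), weights, n_pairs, rl,
                       config$frag_mean, config$frag_sd,
                       config$base_error_rate, config$q_start,
                       config$q_floor, config$q_jitter_sd)
  })
  ids <- sprintf("%s_%06d", id_prefix, seq_len(n_pairs))
  hap_names <- names(haplotypes)[sim$source]
  reads <- data.frame(id = ids, seq1 = sim$seq1, qual1 = sim$qual1,
                      seq2 = sim$seq2, qual2 = sim$qual2,
                      stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
    haplotype = c(hap_names, hap_names),
    start = c(sim$frag_start, sim$frag_end - rl),
    end = c(sim$frag_start + rl, sim$frag_end),
    strand = rep(c("+", "-"), each = n_pairs),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$read_id), , drop = FALSE]
  rownames(truth) <- NULL
  list(reads = reads, truth = truth)
}

#' Simulate a whole-genome sequencing experiment
#'
#' Builds the insertion haplotypes from `config$events`, simulates the
#' paired-end library and returns reads plus both truth tables (per-read
#' origins and the insertion BED).
#'
#' @param refset a [reference_set()] from [build_reference()].
#' @param config a [sim_config()].
#' @return list with `reads`, `truth` (as in [simulate_reads()]),
#'   `truth_bed` (ground-truth insertions, 0-based half-open TSD interval)
#'   and `haplotypes` (the weighted variant set).
#' @export
simulate_wgs <- function(refset, config) {
  haps <- build_haplotypes(refset, config$events, config)
  n_pairs <- as.integer(round(config$depth * haps$genome_len /
                                (2 * config$read_len)))
  sim <- simulate_reads(haps$seqs, haps$weights, config, n_pairs = n_pairs)
  c(sim, list(truth_bed = haps$truth_bed, haplotypes = haps))
}

#' Simulate mutated amplicon clones
#'
#' Emulates Sanger-sequenced plasmid clones of an RT-PCR amplicon carrying
#' deaminase-induced mutations: each clone receives a Poisson(rate x length)
#' number of substitutions, of which a configurable fraction is forced to be
#' plus-strand G>A (drawn from the reference's G positions) and the rest are
#' uniform substitutions at uniform positions. No indels are introduced.
#'
#' @param amplicon_ref amplicon reference sequence (character scalar);
#'   defaults must be supplied by the caller, typically 549 nt.
#' @param config a [sim_config()]; uses `n_mice`, `clones_per_mouse`,
#'   `clone_mut_rate`, `clone_ga_fraction` and the seed.
#' @return list with `clones` (named character vector, names
#'   `"m<mouse>_c<clone>"`) and `truth` (data.frame: clone_id, mouse_id,
#'   pos (0-based), ref, alt).
#' @export
simulate_clones <- function(amplicon_ref, config) {
  rate <- config$clone_mut_rate
  if (rate < 0) stop("clone_mut_rate must be non-negative")
  len <- nchar(amplicon_ref)
  ref_bases <- strsplit(amplicon_ref, "")[[1]]
  g_pos <- which(ref_bases == "G")
  bases <- c("A", "C", "G", "T")
  with_seed(derive_seed(config$seed, "clones"), {
    clones <- character(0)
    truth <- list()
    for (m in seq_len(config$n_mice)) {
      nc_range <- seq(config$clones_per_mouse[1], config$clones_per_mouse[2])
      nc <- nc_range[sample.int(length(nc_range), 1)]
      for (cl in seq_len(nc)) {
        id <- sprintf("m%d_c%d", m, cl)
        n_mut <- rpois(1, rate * len)
        seq_b <- ref_bases
        used <- integer(0)
        n_sig <- min(rbinom(1, n_mut, config$clone_ga_fraction),
                     length(g_pos))
        if (n_sig > 0) {
          pos <- sample(g_pos, n_sig)
          seq_b[pos] <- "A"
          used <- pos
          for (p in pos)
            truth[[length(truth) + 1]] <-
              data.frame(clone_id = id, mouse_id = paste0("m", m),
                         pos = p - 1L, ref = "G", alt = "A",
                         stringsAsFactors = FALSE)
        }
        n_other <- n_mut - n_sig
        if (n_other > 0) {
          avail <- setdiff(seq_len(len), used)
          pos <- sample(avail, min(n_other, length(avail)))
          for (p in pos) {
            alt <- sample(setdiff(bases, seq_b[p]), 1)
            truth[[length(truth) + 1]] <-
              data.frame(clone_id = id, mouse_id = paste0("m", m),
                         pos = p - 1L, ref = ref_bases[p], alt = alt,
                         stringsAsFactors = FALSE)
            seq_b[p] <- alt
          }
        }
        clones[id] <- paste(seq_b, collapse = "")
      }
    }
    truth_df <- if (length(truth)) do.call(rbind, truth) else
      data.frame(clone_id = character(0), mouse_id = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    list(clones = clones, truth = truth_df)
  })
}
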