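# Hypermutation quantification of cloned amplicon sequences: global
# alignment to the amplicon reference, substitution spectra with the
# plus-strand G>A deaminase signature, per-mouse summaries.

#' Global alignment of a clone against the amplicon reference
#'
#' Needleman-Wunsch global alignment with affine gaps (Gotoh): match +1,
#' mismatch -1, first gap base -4, each further gap base -1. Tie-breaking
#' is deterministic: diagonal preferred, then the gap consuming the clone.
#'
#' @param clone,reference sequences over ACGTN (character scalars).
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return list of class `global_alignment`: `aligned1` (clone), `aligned2`
#'   (reference), `score`.
#' @export
global_align <- function(clone, reference, match = 1, mismatch = -1,
                         gap_open = -4, gap_extend = -1) {
  if (nchar(clone) == 0 || nchar(reference) == 0)
    stop("sequences must be non-empty")
  out <- cpp_nw_align(toupper(clone), toupper(reference),
                      match, mismatch, gap_open, gap_extend)
  structure(out, class = "global_alignment")
}

#' Count mutations in an aligned clone/reference pair
#'
#' Substitution columns are tallied into a 4x4 spectrum (reference base ->
#' observed base). Columns containing a gap or an N are excluded from the
#' substitution count; gaps are reported separately. For each plus-strand
#' G>A substitution the preceding reference base (dinucleotide context) is
#' recorded.
#'
#' @param alignment a [global_align()] result (`aligned1` = clone,
#'   `aligned2` = reference).
#' @param clone_id identifier stored in the profile.
#' @return list of class `clone_mutation_profile`: `clone_id`, `n_subs`,
#'   `n_gaps`, `spectrum` (4x4 matrix, rows = reference base), `ga_count`,
#'   `ga_fraction`, `context_counts`.
#' @export
count_mutations <- function(alignment, clone_id = "clone") {
  cl <- strsplit(alignment$aligned1, "")[[1]]
  rf <- strsplit(alignment$aligned2, "")[[1]]
  bases <- c("A", "C", "G", "T")
  spectrum <- matrix(0L, 4, 4, dimnames = list(ref = bases, obs = bases))
  context <- integer(0)
  n_gaps <- sum(cl == "-" | rf == "-")
  prev_ref <- NA_character_
  for (i in seq_along(cl)) {
    r <- rf[i]; c <- cl[i]
    if (r != "-") {
      if (r %in% bases && c %in% bases && r != c) {
        spectrum[r, c] <- spectrum[r, c] + 1L
        if (r == "G" && c == "A") {
          ctx <- if (!is.na(prev_ref)) paste0(prev_ref, "G") else "NG"
          if (is.na(match(ctx, names(context)))) context[ctx] <- 0L
          context[ctx] <- context[ctx] + 1L
        }
      }
      prev_ref <- r
    }
  }
  n_subs <- sum(spectrum)
  ga <- spectrum["G", "A"]
  structure(list(clone_id = clone_id, n_subs = n_subs, n_gaps = n_gaps,
                 spectrum = spectrum, ga_count = ga,
                 ga_fraction = if (n_subs > 0) ga / n_subs else 0,
                 context_counts = context),
            class = "clone_mutation_profile")
}

#' Analyze a set of clones against the amplicon reference
#'
#' Convenience wrapper: aligns each clone ([global_align()]), counts
#' mutations ([count_mutations()]) and assembles a per-clone table. Clone
#' identifiers of the form `"<mouse>_<clone>"` (e.g. `"m1_c3"`) encode the
#' mouse.
#'
#' @param clones named character vector of clone sequences.
#' @param reference the amplicon reference sequence.
#' @return list with `per_clone` data.frame (`clone_id`, `mouse_id`,
#'   `n_subs`, `n_gaps`, `ga_count`, `ga_fraction`), `spectrum` (summed
#'   4x4 matrix) and `profiles` (the individual profiles).
#' @export
analyze_clones <- function(clones, reference) {
  if (is.null(names(clones))) names(clones) <- sprintf("clone_%d",
                                                       seq_along(clones))
  profiles <- lapply(names(clones), function(id)
    count_mutations(global_align(clones[[id]], reference), id))
  per_clone <- data.frame(
    clone_id = vapply(profiles, `[[`, character(1), "clone_id"),
    mouse_id = sub("_[^_]+$", "", names(clones)),
    n_subs = vapply(profiles, `[[`, numeric(1), "n_subs"),
    n_gaps = vapply(profiles, `[[`, numeric(1), "n_gaps"),
    ga_count = vapply(profiles, function(p) as.numeric(p$ga_count),
                      numeric(1)),
    ga_fraction = vapply(profiles, `[[`, numeric(1), "ga_fraction"),
    row.names = NULL, stringsAsFactors = FALSE)
  spectrum <- Reduce(`+`, lapply(profiles, `[[`, "spectrum"))
  list(per_clone = per_clone, spectrum = spectrum, profiles = profiles)
}

#' Per-mouse summaries of clone mutation counts
#'
#' @param per_clone data.frame with `mouse_id` and `n_subs` columns (e.g.
#'   from [analyze_clones()]).
#' @return data.frame with `mouse_id`, `n_clones`, `mean_subs`, `sd_subs`
#'   (sample SD, n - 1 denominator; 0 for a single clone).
#' @export
summarize_mice <- function(per_clone) {
  if (nrow(per_clone) == 0) stop("no clones to summarize")
  out <- lapply(split(per_clone, per_clone$mouse_id), function(g) {
    data.frame(mouse_id = g$mouse_id[1], n_clones = nrow(g),
               mean_subs = mean(g$n_subs),
               sd_subs = if (nrow(g) > 1) sd(g$n_subs) else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full hypermutation analysis from FASTA input
#'
#' The FASTA must contain the amplicon reference as its first record,
#' followed by the clones (ids of the form `"<mouse>_<clone>"`).
#'
#' @param fasta path to the FASTA file.
#' @param outdir optional output directory for per-clone and per-mouse TSVs
#'   and a JSON spectrum.
#' @return list with `per_clone`, `per_mouse` and `spectrum`.
#' @export
analyze_clone_fasta <- function(fasta, outdir = NULL) {
  seqs <- read_fasta(fasta)
  if (length(seqs) < 2) stop("FASTA must contain a reference and clones")
  reference <- seqs[[1]]
  clones <- seqs[-1]
  res <- analyze_clones(clones, reference)
  per_mouse <- summarize_mice(res$per_clone)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.table(res$per_clone, file.path(outdir, "clones.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(per_mouse, file.path(outdir, "mice.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json(list(spectrum = as.data.frame(as.table(res$spectrum))),
               file.path(outdir, "spectrum.json"))
  }
  list(per_clone = res$per_clone, per_mouse = per_mouse,
       spectrum = res$spectrum)
}
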