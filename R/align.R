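# Split-read alignment against the combined host + provirus reference.

#' Alignment parameters
#'
#' @param k seed k-mer length (default 21; must be >= 11).
#' @param min_seg minimum split-segment length in bp (default 25; must be
#'   >= `k`).
#' @param max_mismatch_rate maximum per-segment mismatch rate (default 0.05).
#' @param uniqueness_margin an alignment is unique iff its score exceeds the
#'   best competing placement by at least this many score units (default 5).
#' @param split_penalty score penalty applied once per split (default 2).
#' @param seed_step stride between probed k-mer starts (default 3; the final
#'   k-mer of the read is always probed).
#' @param min_split_score minimum total score for a split to be reported
#'   (default 40).
#' @param full_coverage fraction of the read a single diagonal must cover to
#'   be reported as a full alignment (default 0.95).
#' @return object of class `align_params`.
#' @export
align_params <- function(k = 21L, min_seg = 25L, max_mismatch_rate = 0.05,
                         uniqueness_margin = 5L, split_penalty = 2L,
                         seed_step = 3L, min_split_score = 40L,
                         full_coverage = 0.95) {
  if (k < 11) stop("k must be >= 11")
  if (min_seg < k) stop("min_seg must be >= k")
  structure(list(k = as.integer(k), min_seg = as.integer(min_seg),
                 max_mismatch_rate = max_mismatch_rate,
                 uniqueness_margin = as.integer(uniqueness_margin),
                 split_penalty = as.integer(split_penalty),
                 seed_step = as.integer(seed_step),
                 min_split_score = as.integer(min_split_score),
                 full_coverage = full_coverage),
            class = "align_params")
}

#' Build an exact k-mer index over a reference set
#'
#' Indexes every k-mer position of the forward strand of every contig; the
#' reverse strand is handled at query time via the reverse complement of
#' the read.
#'
#' @param refset a [reference_set()].
#' @param k k-mer length.
#' @return object of class `kmer_index`.
#' @export
build_index <- function(refset, k = 21L) {
  if (k > min(refset$info$length))
    stop("k exceeds the shortest contig length")
  ptr <- cpp_build_index(refset$info$name, unname(refset$seqs), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 names = refset$info$name,
                 lengths = refset$info$length,
                 refset = refset),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("kmer_index: k =", x$k, "over", length(x$names), "contigs (",
      sum(x$lengths), "bp )\n")
  invisible(x)
}

#' Look up a k-mer in the index
#'
#' @param index a [build_index()] result.
#' @param kmer query of length `k` over ACGT.
#' @return data.frame with `contig` (name) and 0-based `pos` of every exact
#'   forward-strand occurrence.
#' @export
kmer_lookup <- function(index, kmer) {
  hits <- cpp_kmer_lookup(index$ptr, kmer)
  data.frame(contig = index$names[hits$contig], pos = hits$pos,
             stringsAsFactors = FALSE)
}

#' Align reads with split (chimeric) detection
#'
#' Seeds are collected on both strands and tallied per (contig, strand,
#' diagonal). A read is reported as a full alignment when a single diagonal
#' covers at least `full_coverage` of the read at a mismatch rate within
#' `max_mismatch_rate`; otherwise the best-scoring two-segment partition
#' (prefix on one diagonal, suffix on another, each segment at least
#' `min_seg` bp) is reported as a split. Reads with no qualifying placement
#' are unmapped. Scoring is match +1, mismatch -1, minus `split_penalty`
#' per split; an alignment is `unique` iff its score beats the best
#' competing placement by `uniqueness_margin`. Junction ties are resolved
#' so that microhomology bases are absorbed by the first (prefix) segment.
#'
#' @param reads character vector of read sequences (names become
#'   `read_id`s; unnamed reads are numbered).
#' @param index a [build_index()] result.
#' @param params an [align_params()].
#' @return data.frame, one row per read, with columns `read_id`, `type`
#'   (`"full"`, `"split"` or `"unmapped"`), per-segment fields
#'   (`contig_a`, `ref_start_a`, `ref_end_a`, `strand_a`, `read_start_a`,
#'   `read_end_a`, `mismatches_a`, and the same with suffix `_b` for the
#'   second split segment), `junction_offset`, `score`, `secondary_score`
#'   and `unique`. All coordinates 0-based half-open.
#' @export
align_reads <- function(reads, index, params = align_params()) {
  ids <- names(reads) %||% sprintf("read_%06d", seq_along(reads))
  res <- cpp_align_batch(index$ptr, toupper(unname(reads)),
                         params$min_seg, params$max_mismatch_rate,
                         params$uniqueness_margin, params$split_penalty,
                         params$seed_step, params$min_split_score,
                         params$full_coverage)
  res$read_id <- ids
  res$type <- c("unmapped", "full", "split")[res$type + 1L]
  res$contig_a <- ifelse(is.na(res$contig_a), NA_character_,
                         index$names[res$contig_a])
  res$contig_b <- ifelse(is.na(res$contig_b), NA_character_,
                         index$names[res$contig_b])
  res[, c("read_id", setdiff(names(res), "read_id"))]
}

#' Align a single read
#'
#' @inheritParams align_reads
#' @param read a single read sequence.
#' @return one-row data.frame as in [align_reads()].
#' @export
align_read <- function(read, index, params = align_params()) {
  align_reads(setNames(read, names(read) %||% "read_000001"), index, params)
}

#' Resolve junction microhomology on a split alignment
#'
#' Applies the leftmost-junction convention: read bases at the junction that
#' match the continuation of the first segment's reference are assigned to
#' the first segment, i.e. the junction offset is pushed to the largest
#' offset at which the first segment still matches its reference exactly.
#' If the first segment can absorb the entire second segment, the split
#' degenerates to a full alignment.
#'
#' @param split a one-row split alignment (from [align_reads()]).
#' @param read the read sequence the split was called on.
#' @param refset the [reference_set()] the index was built over.
#' @return the updated one-row data.frame (possibly with `type = "full"`).
#' @export
resolve_microhomology <- function(split, read, refset) {
  stopifnot(nrow(split) == 1, split$type == "split")
  L <- nchar(read)
  j <- split$junction_offset
  cs <- refset$seqs[[split$contig_a]]
  clen <- nchar(cs)
  repeat {
    if (j >= L) break
    # reference base the first segment would align read position j to
    if (split$strand_a == "+") {
      rp <- split$ref_start_a + (j - split$read_start_a)
      if (rp >= clen) break
      ref_b <- substr(cs, rp + 1, rp + 1)
      rd_b <- substr(read, j + 1, j + 1)
    } else {
      rp <- split$ref_end_a - 1 - (j - split$read_start_a)
      if (rp < 0) break
      ref_b <- substr(cs, rp + 1, rp + 1)
      rd_b <- revcomp(substr(read, j + 1, j + 1))
    }
    if (ref_b != rd_b) break
    j <- j + 1
  }
  if (j >= L) {
    # degenerate: the first segment explains the whole read
    split$type <- "full"
    split$read_end_a <- L
    if (split$strand_a == "+") {
      split$ref_end_a <- split$ref_start_a + L
    } else {
      split$ref_start_a <- split$ref_end_a - L
    }
    split[, grep("_b$", names(split))] <- NA
    split$junction_offset <- NA_integer_
    return(split)
  }
  if (j != split$junction_offset) {
    d <- j - split$junction_offset
    split$read_end_a <- j
    split$read_start_b <- j
    if (split$strand_a == "+") split$ref_end_a <- split$ref_end_a + d
    else split$ref_start_a <- split$ref_start_a - d
    if (split$strand_b == "+") split$ref_start_b <- split$ref_start_b + d
    else split$ref_end_b <- split$ref_end_b - d
    split$junction_offset <- j
  }
  split
}

#' Write alignments to a SAM file
#'
#' Full alignments become primary records; the second segment of a split is
#' written as a supplementary record (flag 2048) and both records carry
#' `SA` cross-reference tags. Unmapped reads get flag-4 records. Positions
#' are 1-based per SAM convention; the header carries contig lengths.
#'
#' @param aln alignment data.frame from [align_reads()].
#' @param reads named character vector of the aligned read sequences.
#' @param refset the [reference_set()] aligned against.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, reads, refset, path) {
  if (any(!stats::na.omit(c(aln$contig_a, aln$contig_b)) %in%
          refset$info$name))
    stop("alignment references an unknown contig")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refset$info$name,
                     refset$info$length), con)
  sam_seg <- function(id, seq, contig, pos, strand, cigar, flag, mapq,
                      nm, sa = NULL) {
    if (strand == "-") {
      seq <- revcomp(seq)
      flag <- bitwOr(flag, 16L)
    }
    rec <- paste(id, flag, contig, pos + 1L, mapq, cigar, "*", 0L, 0L,
                 seq, "*", paste0("NM:i:", nm), sep = "\t")
    if (!is.null(sa)) rec <- paste(rec, paste0("SA:Z:", sa), sep = "\t")
    rec
  }
  cig <- function(pre, mlen, post, strand) {
    # CIGAR is in reference orientation: clips swap on the minus strand
    if (strand == "-") { tmp <- pre; pre <- post; post <- tmp }
    paste0(if (pre > 0) paste0(pre, "S"), mlen, "M",
           if (post > 0) paste0(post, "S"))
  }
  for (i in seq_len(nrow(aln))) {
    a <- aln[i, ]
    seq <- reads[[a$read_id]]
    L <- nchar(seq)
    if (a$type == "unmapped") {
      writeLines(paste(a$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                       seq, "*", sep = "\t"), con)
      next
    }
    mapq <- if (isTRUE(a$unique)) 60L else 0L
    if (a$type == "full") {
      cigar <- cig(a$read_start_a, a$read_end_a - a$read_start_a,
                   L - a$read_end_a, a$strand_a)
      writeLines(sam_seg(a$read_id, seq, a$contig_a, a$ref_start_a,
                         a$strand_a, cigar, 0L, mapq, a$mismatches_a), con)
    } else {
      ca <- cig(0L, a$read_end_a, L - a$read_end_a, a$strand_a)
      cb <- cig(a$read_start_b, L - a$read_start_b, 0L, a$strand_b)
      sa_a <- sprintf("%s,%d,%s,%s,%d,%d;", a$contig_b, a$ref_start_b + 1L,
                      a$strand_b, cb, mapq, a$mismatches_b)
      sa_b <- sprintf("%s,%d,%s,%s,%d,%d;", a$contig_a, a$ref_start_a + 1L,
                      a$strand_a, ca, mapq, a$mismatches_a)
      writeLines(sam_seg(a$read_id, seq, a$contig_a, a$ref_start_a,
                         a$strand_a, ca, 0L, mapq, a$mismatches_a, sa_a), con)
      writeLines(sam_seg(a$read_id, seq, a$contig_b, a$ref_start_b,
                         a$strand_b, cb, 2048L, mapq, a$mismatches_b, sa_b),
                 con)
    }
  }
  invisible(path)
}

#' Write split alignments to a TSV
#'
#' @param aln alignment data.frame from [align_reads()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splits_tsv <- function(aln, path) {
  sp <- aln[aln$type == "split",
            c("read_id", "contig_a", "ref_start_a", "strand_a",
              "contig_b", "ref_start_b", "strand_b", "junction_offset",
              "unique")]
  write.table(sp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
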