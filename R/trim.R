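# Quality trimming (3' partial-sum rule) and pair length filtering.

#' Trimming configuration
#'
#' @param quality_cutoff Phred cutoff for 3' quality trimming (default 20).
#' @param min_len minimum mate length; pairs in which either trimmed mate is
#'   shorter are discarded (default 20 bp).
#' @param adapter optional adapter sequence removed by exact-match clipping
#'   before quality trimming.
#' @return object of class `trim_config`.
#' @export
trim_config <- function(quality_cutoff = 20L, min_len = 20L, adapter = NULL) {
  if (quality_cutoff < 0 || quality_cutoff > 41)
    stop("quality_cutoff must be in [0, 41]")
  if (min_len < 1) stop("min_len must be >= 1")
  structure(list(quality_cutoff = as.integer(quality_cutoff),
                 min_len = as.integer(min_len), adapter = adapter),
            class = "trim_config")
}

#' Quality-trim a read from the 3' end
#'
#' Implements the standard 3' partial-sum rule: with
#' `S(i) = sum_{j >= i} (q_j - cutoff)`, the read is cut at the position
#' minimising `S` (ties broken toward the smaller position, i.e. trimming
#' more), provided that minimum is negative; otherwise the read is returned
#' unchanged.
#'
#' @param seq read sequence (character scalar).
#' @param quals integer Phred scores, one per base.
#' @param cutoff Phred cutoff.
#' @return list with trimmed `seq` and `quals`.
#' @export
quality_trim <- function(seq, quals, cutoff = 20L) {
  if (nchar(seq) != length(quals))
    stop("sequence and quality lengths differ")
  if (length(quals) == 0) return(list(seq = seq, quals = quals))
  keep <- cpp_trim_cut(as.integer(quals), as.integer(cutoff))
  list(seq = substr(seq, 1, keep), quals = quals[seq_len(keep)])
}

#' Keep or discard a trimmed read pair by length
#'
#' A pair is discarded iff at least one mate is shorter than `min_len`.
#'
#' @param r1,r2 mate sequences (character scalars).
#' @param min_len minimum length in bp.
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
filter_pair <- function(r1, r2, min_len = 20L) {
  nchar(r1) >= min_len && nchar(r2) >= min_len
}

# Exact-match adapter clipping: the read is truncated at the first exact
# occurrence of the adapter (full error-tolerant adapter alignment is out
# of scope; synthetic reads carry no adapters by default).
clip_adapter <- function(seq, qual, adapter) {
  hit <- regexpr(adapter, seq, fixed = TRUE)
  keep <- ifelse(hit > 0, hit - 1L, nchar(seq))
  list(seq = substr(seq, 1, keep), qual = substr(qual, 1, keep))
}

#' Trim a stream of read pairs
#'
#' Applies optional exact-match adapter clipping, then 3' quality trimming
#' ([quality_trim()]) to each mate, then the pair length filter
#' ([filter_pair()]).
#'
#' @param reads data.frame with columns `id`, `seq1`, `qual1`, `seq2`,
#'   `qual2` (qualities Phred+33), e.g. from [read_fastq()] pairs or
#'   [simulate_reads()].
#' @param config a [trim_config()].
#' @return list with `reads` (kept pairs, trimmed) and `stats` (class
#'   `trim_stats`: pairs_in, pairs_kept, pairs_discarded, bases_in,
#'   bases_kept).
#' @export
trim_fastq <- function(reads, config = trim_config()) {
  stopifnot(all(c("id", "seq1", "qual1", "seq2", "qual2") %in% names(reads)))
  s1 <- reads$seq1; q1 <- reads$qual1
  s2 <- reads$seq2; q2 <- reads$qual2
  if (!is.null(config$adapter)) {
    a1 <- clip_adapter(s1, q1, config$adapter)
    a2 <- clip_adapter(s2, q2, config$adapter)
    s1 <- a1$seq; q1 <- a1$qual
    s2 <- a2$seq; q2 <- a2$qual
  }
  tr <- cpp_trim_pairs(s1, q1, s2, q2, config$quality_cutoff, config$min_len)
  kept <- data.frame(id = reads$id[tr$keep],
                     seq1 = tr$seq1[tr$keep], qual1 = tr$qual1[tr$keep],
                     seq2 = tr$seq2[tr$keep], qual2 = tr$qual2[tr$keep],
                     stringsAsFactors = FALSE)
  stats <- structure(list(pairs_in = nrow(reads),
                          pairs_kept = sum(tr$keep),
                          pairs_discarded = sum(!tr$keep),
                          bases_in = tr$bases_in,
                          bases_kept = tr$bases_kept),
                     class = "trim_stats")
  list(reads = kept, stats = stats)
}

#' @export
print.trim_stats <- function(x, ...) {
  cat(sprintf("trim: %d pairs in, %d kept, %d discarded (%.4g%% of bases kept)\n",
              x$pairs_in, x$pairs_kept, x$pairs_discarded,
              100 * x$bases_kept / max(1, x$bases_in)))
  invisible(x)
}

#' Trim FASTQ files on disk
#'
#' File-based wrapper around [trim_fastq()].
#'
#' @param in1,in2 input FASTQ paths (mate 1, mate 2).
#' @param out1,out2 output FASTQ paths.
#' @param config a [trim_config()].
#' @param stats_path optional path for a JSON stats summary.
#' @return the `trim_stats`, invisibly.
#' @export
trim_fastq_files <- function(in1, in2, out1, out2, config = trim_config(),
                             stats_path = NULL) {
  r1 <- read_fastq(in1)
  r2 <- read_fastq(in2)
  if (nrow(r1) != nrow(r2)) stop("mate files differ in record count")
  reads <- data.frame(id = sub("/[12]$", "", r1$id),
                      seq1 = r1$seq, qual1 = r1$qual,
                      seq2 = r2$seq, qual2 = r2$qual,
                      stringsAsFactors = FALSE)
  out <- trim_fastq(reads, config)
  write_fastq(paste0(out$reads$id, "/1"), out$reads$seq1, out$reads$qual1, out1)
  write_fastq(paste0(out$reads$id, "/2"), out$reads$seq2, out$reads$qual2, out2)
  if (!is.null(stats_path)) write_json(unclass(out$stats), stats_path)
  invisible(out$stats)
}
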