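# File I/O: FASTA/FASTQ through Biostrings, BED through rtracklayer,
# JSON through jsonlite. All genomic coordinates are 0-based half-open
# internally; conversion to 1-based happens only at these boundaries.

#' Read a FASTA file
#'
#' @param path path to a FASTA file (gzip transparent).
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path path to a FASTQ file (gzip transparent).
#' @return data.frame with columns `id`, `seq`, `qual` (Phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param id,seq,qual parallel character vectors (qualities Phred+33).
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  q <- Biostrings::BStringSet(qual)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path.
#' @return data.frame with 0-based half-open `start`/`end`, plus `name`,
#'   `score`, `strand` when present.
#' @export
read_bed <- function(path) {
  g <- rtracklayer::import(path, format = "BED")
  out <- data.frame(contig = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g) - 1L,
                    end = GenomicRanges::end(g),
                    stringsAsFactors = FALSE)
  if (!is.null(g$name)) out$name <- g$name
  if (!is.null(g$score)) out$score <- g$score
  st <- as.character(GenomicRanges::strand(g))
  if (any(st != "*")) out$strand <- st
  out
}

#' Write intervals to a BED file
#'
#' @param df data.frame with `contig`, 0-based half-open `start`/`end`, and
#'   optional `name`, `score`, `strand` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  if (nrow(df) == 0) {
    file.create(path)
    return(invisible(path))
  }
  g <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (!is.null(df$strand)) df$strand else "*")
  if (!is.null(df$name)) g$name <- df$name
  if (!is.null(df$score)) g$score <- df$score
  rtracklayer::export(g, path, format = "BED")
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write the read truth table
#'
#' One row per simulated mate: `read_id`, `haplotype`, 0-based half-open
#' `start`/`end` of the source fragment span covered by the mate, `strand`.
#'
#' @param truth data.frame as returned in `simulate_wgs()$truth`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
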