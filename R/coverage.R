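# Sequencing-depth summaries: per-base depth profiles, mean depth and
# coverage breadth at thresholds.

#' Per-contig depth profiles from alignments
#'
#' Depth at a base is the number of aligned segments overlapping it; both
#' mates and both segments of a split count. Built on [IRanges::coverage()].
#'
#' @param aln alignment data.frame from [align_reads()] (rows of type
#'   `"unmapped"` are ignored).
#' @param refset the [reference_set()] aligned against.
#' @return named [IRanges::RleList]-like list of per-contig depth vectors
#'   (run-length encoded), one per contig in `refset`.
#' @export
depth_profile <- function(aln, refset) {
  segs <- rbind(
    data.frame(contig = aln$contig_a, start = aln$ref_start_a,
               end = aln$ref_end_a, stringsAsFactors = FALSE),
    data.frame(contig = aln$contig_b, start = aln$ref_start_b,
               end = aln$ref_end_b, stringsAsFactors = FALSE))
  segs <- segs[!is.na(segs$contig), , drop = FALSE]
  lens <- setNames(refset$info$length, refset$info$name)
  if (nrow(segs)) {
    bad <- segs$start < 0 | segs$end > lens[segs$contig]
    if (any(bad)) stop("alignment segment outside contig bounds")
  }
  out <- lapply(refset$info$name, function(cn) {
    s <- segs[segs$contig == cn, , drop = FALSE]
    if (nrow(s) == 0)
      return(S4Vectors::Rle(0L, lens[[cn]]))
    IRanges::coverage(IRanges::IRanges(start = s$start + 1L, end = s$end),
                      width = lens[[cn]])
  })
  setNames(out, refset$info$name)
}

#' Summarize depth profiles into mean depth and breadth
#'
#' Mean depth is total aligned bases divided by genome length; breadth at
#' threshold `t` is the fraction of bases with depth at least `t`. The
#' provirus contig is excluded from the genome denominator by default, as
#' depth metrics describe the host genome rather than the vector.
#'
#' @param profile per-contig depth list from [depth_profile()].
#' @param refset the [reference_set()].
#' @param thresholds integer depth thresholds for breadth (default 4).
#' @param include_provirus include the provirus contig in the genome-wide
#'   metrics (default `FALSE`).
#' @return object of class `coverage_summary`: `mean_depth`, `breadth`
#'   (named by threshold), `per_contig` data.frame, `genome_length`.
#' @export
coverage_summary <- function(profile, refset, thresholds = 4L,
                             include_provirus = FALSE) {
  info <- refset$info
  keep <- if (include_provirus) info$name else
    info$name[!info$is_provirus]
  if (length(keep) == 0 || sum(info$length[info$name %in% keep]) == 0)
    stop("empty genome")
  per_contig <- data.frame(
    contig = info$name,
    length = info$length,
    mean_depth = vapply(info$name, function(cn)
      sum(as.numeric(S4Vectors::runValue(profile[[cn]]) *
                       S4Vectors::runLength(profile[[cn]]))) /
        info$length[info$name == cn], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  glen <- sum(info$length[info$name %in% keep])
  total_bases <- sum(vapply(keep, function(cn)
    sum(as.numeric(S4Vectors::runValue(profile[[cn]]) *
                     S4Vectors::runLength(profile[[cn]]))), numeric(1)))
  breadth <- vapply(thresholds, function(t) {
    covered <- sum(vapply(keep, function(cn) {
      r <- profile[[cn]]
      sum(as.numeric(S4Vectors::runLength(r)[S4Vectors::runValue(r) >= t]))
    }, numeric(1)))
    covered / glen
  }, numeric(1))
  structure(list(mean_depth = total_bases / glen,
                 breadth = setNames(breadth, as.character(thresholds)),
                 per_contig = per_contig,
                 genome_length = glen),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage: mean depth %.2fx over %d bp\n",
              x$mean_depth, x$genome_length))
  for (t in names(x$breadth))
    cat(sprintf("  breadth >= %sx: %.2f%%\n", t, 100 * x$breadth[[t]]))
  invisible(x)
}

#' Write a coverage summary to disk
#'
#' @param summ a [coverage_summary()].
#' @param outdir output directory.
#' @return output paths, invisibly.
#' @export
write_coverage <- function(summ, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- file.path(outdir, "coverage_per_contig.tsv")
  write.table(summ$per_contig, tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  json <- file.path(outdir, "coverage_summary.json")
  write_json(list(mean_depth = summ$mean_depth,
                  breadth = as.list(summ$breadth),
                  genome_length = summ$genome_length), json)
  invisible(list(tsv = tsv, json = json))
}
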