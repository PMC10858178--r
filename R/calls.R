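# Trans-split extraction, discard rules and breakpoint clustering.

#' Integration-calling parameters
#'
#' @param cluster_window maximum gap (bp) between neighbouring breakpoints
#'   merged into one call by single-linkage clustering (default 300, about
#'   twice the read length).
#' @param require_unique keep only uniquely mapped splits (default `TRUE`).
#' @return object of class `call_params`.
#' @export
call_params <- function(cluster_window = 300L, require_unique = TRUE) {
  if (cluster_window < 1) stop("cluster_window must be >= 1")
  structure(list(cluster_window = as.integer(cluster_window),
                 require_unique = isTRUE(require_unique)),
            class = "call_params")
}

#' Extract trans splits (host x provirus chimeras)
#'
#' Retains split alignments with exactly one segment on the provirus contig
#' and the other on any host contig, assigns host/provirus roles, and
#' annotates each split with its host breakpoint, whether the provirus
#' segment covers a terminal UTR, and whether the host contig is placed.
#'
#' The host breakpoint is the host base adjacent to the junction: for a
#' host-side first segment, the last host base before the provirus segment;
#' for a host-side second segment, the first host base after it.
#'
#' @param aln alignment data.frame from [align_reads()].
#' @param refset the [reference_set()] aligned against (must contain a
#'   provirus contig with UTR annotation).
#' @param params a [call_params()]; with `require_unique` only unique
#'   splits are retained.
#' @return data.frame of trans splits: `read_id`, `host_contig`,
#'   `host_start`, `host_end`, `host_strand`, `host_side` (`"a"` or `"b"`),
#'   `host_breakpoint` (0-based), `pv_start`, `pv_end`, `pv_strand`,
#'   `covers_utr`, `host_placed`, `unique`.
#' @export
extract_trans_splits <- function(aln, refset, params = call_params()) {
  pv <- refset$provirus_name
  if (is.na(pv) || !pv %in% refset$info$name)
    stop("reference set has no provirus contig")
  utr5 <- refset$annotation$utr5
  utr3 <- refset$annotation$utr3
  sp <- aln[aln$type == "split", , drop = FALSE]
  if (params$require_unique) sp <- sp[isTRUE_v(sp$unique), , drop = FALSE]
  a_pv <- sp$contig_a == pv
  b_pv <- sp$contig_b == pv
  sp <- sp[xor(a_pv, b_pv), , drop = FALSE]
  if (nrow(sp) == 0) return(empty_trans_splits())
  a_pv <- sp$contig_a == pv
  host_side <- ifelse(a_pv, "b", "a")
  pick <- function(col) ifelse(host_side == "a", sp[[paste0(col, "_a")]],
                               sp[[paste0(col, "_b")]])
  pickp <- function(col) ifelse(host_side == "a", sp[[paste0(col, "_b")]],
                                sp[[paste0(col, "_a")]])
  host_contig <- pick("contig")
  host_start <- pick("ref_start"); host_end <- pick("ref_end")
  host_strand <- pick("strand")
  pv_start <- pickp("ref_start"); pv_end <- pickp("ref_end")
  pv_strand <- pickp("strand")
  # host breakpoint: last host base before the provirus (host-side first
  # segment) or first host base after it (host-side second segment), in
  # reference coordinates of the read's own orientation
  host_breakpoint <- ifelse(
    host_side == "a",
    ifelse(host_strand == "+", host_end - 1L, host_start),
    ifelse(host_strand == "+", host_start, host_end - 1L))
  covers_utr <- (pv_start < utr5[2] & pv_end > utr5[1]) |
    (pv_start < utr3[2] & pv_end > utr3[1])
  placed <- setNames(refset$info$placed, refset$info$name)
  data.frame(read_id = sp$read_id, host_contig = host_contig,
             host_start = host_start, host_end = host_end,
             host_strand = host_strand, host_side = host_side,
             host_breakpoint = as.integer(host_breakpoint),
             pv_start = pv_start, pv_end = pv_end, pv_strand = pv_strand,
             covers_utr = covers_utr,
             host_placed = unname(placed[host_contig]),
             unique = sp$unique,
             row.names = NULL, stringsAsFactors = FALSE)
}

isTRUE_v <- function(x) !is.na(x) & x

empty_trans_splits <- function() {
  data.frame(read_id = character(0), host_contig = character(0),
             host_start = integer(0), host_end = integer(0),
             host_strand = character(0), host_side = character(0),
             host_breakpoint = integer(0), pv_start = integer(0),
             pv_end = integer(0), pv_strand = character(0),
             covers_utr = logical(0), host_placed = logical(0),
             unique = logical(0), stringsAsFactors = FALSE)
}

# Median breakpoint with ties broken toward the lower coordinate: for an
# even member count the lower of the two central values is taken.
median_low <- function(x) {
  s <- sort(x)
  s[(length(s) + 1L) %/% 2L]
}

#' Cluster trans splits into integration calls
#'
#' Single-linkage clustering of host breakpoints per host contig: sorted
#' breakpoints are merged while the gap to the previous member is at most
#' `cluster_window`. Each cluster becomes one call with `support` equal to
#' the member read count, `breakpoint` the median member breakpoint (ties
#' toward the lower coordinate) and `span` the member min/max.
#'
#' @param splits trans splits from [extract_trans_splits()].
#' @param params a [call_params()].
#' @return data.frame of calls: `host_contig`, `breakpoint`, `span_start`,
#'   `span_end`, `support`, `singular`, `utr_supported`, `host_placed`,
#'   `status` (`NA` until [filter_calls()]), plus `member_ids`
#'   (comma-separated read ids).
#' @export
cluster_splits <- function(splits, params = call_params()) {
  if (nrow(splits) == 0) return(empty_calls())
  out <- list()
  for (cn in unique(splits$host_contig)) {
    s <- splits[splits$host_contig == cn, , drop = FALSE]
    s <- s[order(s$host_breakpoint), , drop = FALSE]
    gaps <- diff(s$host_breakpoint)
    cl <- cumsum(c(1L, as.integer(gaps > params$cluster_window)))
    for (g in unique(cl)) {
      m <- s[cl == g, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        host_contig = cn,
        breakpoint = median_low(m$host_breakpoint),
        span_start = min(m$host_breakpoint),
        span_end = max(m$host_breakpoint),
        support = nrow(m),
        singular = nrow(m) == 1L,
        utr_supported = sum(m$covers_utr),
        host_placed = m$host_placed[1],
        status = NA_character_,
        member_ids = paste(m$read_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$host_contig, res$breakpoint), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_calls <- function() {
  data.frame(host_contig = character(0), breakpoint = integer(0),
             span_start = integer(0), span_end = integer(0),
             support = integer(0), singular = logical(0),
             utr_supported = integer(0), host_placed = logical(0),
             status = character(0), member_ids = character(0),
             stringsAsFactors = FALSE)
}

#' Apply the discard rules to clustered calls
#'
#' A call is `discarded_unplaced` when its host contig is an unplaced
#' scaffold (applied to all calls, not only singletons), otherwise
#' `discarded_no_utr` when it is singular (support 1) and none of its
#' members' provirus segments cover a terminal UTR, otherwise `pass`.
#' Discarded calls are retained in the output with their status so the
#' filtering is auditable.
#'
#' @param calls calls from [cluster_splits()].
#' @return the calls with `status` filled in.
#' @export
filter_calls <- function(calls) {
  if (nrow(calls) == 0) return(calls)
  calls$status <- ifelse(
    !calls$host_placed, "discarded_unplaced",
    ifelse(calls$singular & calls$utr_supported == 0,
           "discarded_no_utr", "pass"))
  calls
}

#' Report integration calls to disk
#'
#' Writes passing calls as BED (0-based half-open span), all calls as a TSV
#' (1-based breakpoint) and a JSON summary with per-status counts. When a
#' ground-truth insertion BED is supplied, the summary additionally reports
#' the breakpoint error of the nearest passing call per true event.
#'
#' @param calls filtered calls from [filter_calls()].
#' @param refset the [reference_set()].
#' @param outdir output directory (created if needed).
#' @param truth_bed optional data.frame of true insertions (`contig`,
#'   0-based `start`, `end`), e.g. `simulate_wgs()$truth_bed` or
#'   [read_bed()] output.
#' @return list with the `summary` (also written as JSON) and output paths,
#'   invisibly.
#' @export
report_calls <- function(calls, refset, outdir, truth_bed = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  pass <- calls[isTRUE_v(calls$status == "pass"), , drop = FALSE]
  bed_path <- file.path(outdir, "integration_calls.bed")
  write_bed(if (nrow(pass)) data.frame(
    contig = pass$host_contig, start = pass$span_start,
    end = pass$span_end + 1L,
    name = sprintf("call_%d", seq_len(nrow(pass))),
    score = pass$support, stringsAsFactors = FALSE) else pass[0, 0],
    bed_path)
  tsv_path <- file.path(outdir, "integration_calls.tsv")
  tsv <- calls[, c("host_contig", "breakpoint", "span_start", "span_end",
                   "support", "utr_supported", "status")]
  tsv$breakpoint <- tsv$breakpoint + 1L # 1-based for the TSV report
  write.table(tsv, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    n_calls = nrow(calls),
    n_pass = sum(calls$status == "pass"),
    n_discarded_no_utr = sum(calls$status == "discarded_no_utr"),
    n_discarded_unplaced = sum(calls$status == "discarded_unplaced"),
    splits_total = sum(calls$support),
    splits_in_passing_calls = sum(pass$support))
  if (!is.null(truth_bed) && nrow(truth_bed) > 0) {
    cmp <- lapply(seq_len(nrow(truth_bed)), function(i) {
      tr <- truth_bed[i, ]
      cand <- pass[pass$host_contig == tr$contig, , drop = FALSE]
      if (nrow(cand) == 0)
        return(list(contig = tr$contig, position = tr$start,
                    detected = FALSE, breakpoint_error = NA))
      err <- min(abs(cand$breakpoint - tr$start))
      list(contig = tr$contig, position = tr$start, detected = TRUE,
           breakpoint_error = err)
    })
    summary$truth_comparison <- cmp
  }
  json_path <- file.path(outdir, "integration_summary.json")
  write_json(summary, json_path)
  invisible(list(summary = summary, bed = bed_path, tsv = tsv_path,
                 json = json_path))
}
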