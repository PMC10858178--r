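# Independent oracles used across the suite. These are deliberately naive
# (exhaustive / brute-force) re-derivations of the rules, kept free of any
# code path they are checking.

# 3' partial-sum trimming: exhaustive search over all cut points.
trim_oracle <- function(q, cutoff) {
  L <- length(q)
  if (L == 0) return(0L)
  S <- vapply(seq_len(L) - 1L, function(i) sum(q[(i + 1):L] - cutoff),
              numeric(1))
  if (min(S) < 0) which(S == min(S))[1] - 1L else L
}

# Brute-force per-base depth counting over explicit segment lists.
depth_oracle <- function(segs, len) {
  d <- integer(len)
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]
    if (e > s) d[(s + 1):e] <- d[(s + 1):e] + 1L
  }
  d
}

# Affine-gap global alignment score by direct three-state DP (Gotoh),
# written independently of the package's aligned-string implementation.
nw_score_oracle <- function(a, b, match = 1, mism = -1, open = -4,
                            ext = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n) + 1) X[i, 1] <- open + (i - 2) * ext
  for (j in seq_len(m) + 1) Y[1, j] <- open + (j - 2) * ext
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mism
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + ext,
                     Y[i - 1, j] + open)
      Y[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + open,
                     Y[i, j - 1] + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Brute-force best alignment score of a read over a small reference set,
# scanning every position on both strands: best qualifying full placement,
# else best two-segment split under the same scoring rules as the aligner
# (match +1, mismatch -1, per-segment mismatch-rate cap, split penalty).
# Only unclipped placements are scanned, so reads must not hang off
# contig ends.
brute_align_score <- function(read, refset, min_seg = 25L, max_mm = 0.05,
                              split_pen = 2L, full_cov = 0.95) {
  L <- nchar(read)
  r <- utf8ToInt(read)
  best_full <- -Inf
  bestpref <- rep(-Inf, L + 1)  # bestpref[j+1]: best prefix [0, j) score
  bestsuf <- rep(-Inf, L + 1)   # bestsuf[j+1]: best suffix [j, L) score
  bestpref[1] <- 0
  bestsuf[L + 1] <- 0
  pad <- utf8ToInt(strrep("N", L)) # never matches; lets segments sit at
                                   # contig ends with the rest of the read
                                   # window hanging outside
  for (cn in names(refset$seqs)) {
    for (strand in c("+", "-")) {
      g <- refset$seqs[[cn]]
      gi <- c(pad, utf8ToInt(if (strand == "+") g else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(g)))),
        pad)
      noff <- length(gi) - L + 1
      if (noff < 1) next
      mm <- integer(noff)
      for (j in seq_len(L)) {
        mm <- mm + as.integer(gi[j:(j + noff - 1)] != r[j])
        sc <- j - 2 * mm
        sc[mm > max_mm * j] <- -Inf
        bestpref[j + 1] <- max(bestpref[j + 1], sc)
      }
      full <- L - 2 * mm
      full[mm > max_mm * L] <- -Inf
      best_full <- max(best_full, full)
      mm <- integer(noff)
      for (j in rev(seq_len(L))) {
        mm <- mm + as.integer(gi[j:(j + noff - 1)] != r[j])
        sc <- (L - j + 1) - 2 * mm
        sc[mm > max_mm * (L - j + 1)] <- -Inf
        bestsuf[j] <- max(bestsuf[j], sc)
      }
    }
  }
  best_split <- -Inf
  if (L >= 2 * min_seg) {
    for (j in min_seg:(L - min_seg))
      best_split <- max(best_split,
                        bestpref[j + 1] + bestsuf[j + 1] - split_pen)
  }
  # the aligner reports a qualifying full placement in preference to splits
  if (is.finite(best_full)) best_full else best_split
}

# Rule-by-rule re-derivation of the discard logic, applied per split and
# then aggregated per cluster, independent of filter_calls().
filter_oracle <- function(splits, window = 300L) {
  out <- list()
  for (cn in unique(splits$host_contig)) {
    s <- splits[splits$host_contig == cn, , drop = FALSE]
    s <- s[order(s$host_breakpoint), , drop = FALSE]
    grp <- cumsum(c(1, as.integer(diff(s$host_breakpoint) > window)))
    for (g in unique(grp)) {
      m <- s[grp == g, , drop = FALSE]
      status <- if (!m$host_placed[1]) "discarded_unplaced"
      else if (nrow(m) == 1 && !any(m$covers_utr)) "discarded_no_utr"
      else "pass"
      out[[length(out) + 1]] <- data.frame(
        host_contig = cn, n = nrow(m), status = status,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
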