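#' Remove exact duplicate candidates across tools
#'
#' Candidates reported identically (same interval, motif and unit
#' count) by several detectors are collapsed into one entry whose
#' `tools` field is the union of the source tools.
#'
#' @param candidates Candidate data frame.
#' @return A list with `candidates` (deduplicated data frame) and
#'   `per_tool_counts` (named integer vector of raw input counts).
#' @export
dedupe_exact <- function(candidates) {
  tools_in <- unlist(strsplit(candidates$tools, ",", fixed = TRUE))
  per_tool <- if (length(tools_in)) table(tools_in) else table(character())
  if (nrow(candidates) == 0L)
    return(list(candidates = candidates,
                per_tool_counts = stats::setNames(integer(), character())))
  key <- paste(candidates$seqid, candidates$start, candidates$end,
               candidates$strand, candidates$motif, candidates$units,
               sep = "\r")
  groups <- split(seq_len(nrow(candidates)), factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(groups, function(idx) {
    row <- candidates[idx[1], , drop = FALSE]
    row$tools <- paste(sort(unique(unlist(
      strsplit(candidates$tools[idx], ",", fixed = TRUE)))), collapse = ",")
    row
  }))
  rownames(out) <- NULL
  list(candidates = out,
       per_tool_counts = stats::setNames(as.integer(per_tool), names(per_tool)))
}

# overlap fraction of a candidate pair, relative to the shorter
# ("shorter"), the longer... ("either" = max of the two fractions,
# "both" = min).
overlap_fraction <- function(s1, e1, s2, e2, mode = "shorter") {
  ov <- max(0L, min(e1, e2) - max(s1, s2))
  f1 <- ov / (e1 - s1)
  f2 <- ov / (e2 - s2)
  switch(mode,
         shorter = ov / min(e1 - s1, e2 - s2),
         either = max(f1, f2),
         both = min(f1, f2))
}

#' Iteratively remove heavily overlapping candidates
#'
#' Applies to a fixed point the rule: if two repeats overlap by more
#' than 50% of their size, drop the shorter one (tie by size: drop the
#' one with the larger motif). "Their size" is interpreted against the
#' shorter member by default (configurable). Pairs are processed in
#' order of decreasing overlap fraction, ties broken by leftmost start,
#' which makes the output deterministic.
#'
#' @param candidates Candidate data frame on one reference.
#' @param threshold Overlap fraction above which a pair conflicts
#'   (default 0.5, strict).
#' @param size_mode `"shorter"` (default), `"either"` or `"both"`:
#'   which member's size the overlap is compared against.
#' @return The surviving candidates, original order preserved.
#' @export
iterative_overlap_removal <- function(candidates, threshold = 0.5,
                                      size_mode = c("shorter", "either", "both")) {
  size_mode <- match.arg(size_mode)
  n <- nrow(candidates)
  if (n <= 1L) return(candidates)
  alive <- rep(TRUE, n)
  st <- candidates$start; en <- candidates$end
  sq <- candidates$seqid
  mlen <- nchar(candidates$motif)
  len <- en - st
  repeat {
    idx <- which(alive)
    if (length(idx) <= 1L) break
    best <- NULL; best_frac <- threshold; best_left <- Inf
    for (a in seq_along(idx)[-length(idx)]) {
      i <- idx[a]
      for (b in seq.int(a + 1L, length(idx))) {
        j <- idx[b]
        if (sq[i] != sq[j]) next
        fr <- overlap_fraction(st[i], en[i], st[j], en[j], size_mode)
        lm <- min(st[i], st[j])
        if (fr > best_frac ||
            (fr == best_frac && !is.null(best) && lm < best_left)) {
          best <- c(i, j); best_frac <- fr; best_left <- lm
        }
      }
    }
    if (is.null(best)) break
    i <- best[1]; j <- best[2]
    drop <- if (len[i] != len[j]) {
      if (len[i] < len[j]) i else j             # shorter goes
    } else if (mlen[i] != mlen[j]) {
      if (mlen[i] > mlen[j]) i else j           # tie: larger motif goes
    } else {
      if (st[i] > st[j]) i else j               # full tie: later start goes
    }
    alive[drop] <- FALSE
  }
  candidates[alive, , drop = FALSE]
}

#' Flag low-quality candidates
#'
#' Rejects candidates that would pollute the catalog: loci containing a
#' stretch of at least `n_stretch` consecutive `N` (`N_STRETCH`),
#' single-base motifs (`MOTIF_1`), duplicate predictions spanning the
#' same nucleotides with different motif/unit parameters (`DUPLICATE`;
#' the candidate whose motif-length x unit-count best matches the span
#' survives, ties to the smaller motif), and spurious detector output
#' (`SPURIOUS`): unit count below 2, or a motif matching the locus at
#' under 50% identity in every tiling frame.
#'
#' @param candidates Candidate data frame with `sequence` populated.
#' @param n_stretch Minimum run of `N` that disqualifies (default 10).
#' @return List with `kept` (data frame) and `rejected` (data frame
#'   with a `reason` column).
#' @export
apply_low_quality_filters <- function(candidates, n_stretch = 10L) {
  n <- nrow(candidates)
  reason <- rep(NA_character_, n)
  if (n > 0L) {
    has_n <- grepl(paste0("N{", n_stretch, "}"), candidates$sequence)
    reason[has_n] <- "N_STRETCH"
    reason[is.na(reason) & nchar(candidates$motif) == 1L] <- "MOTIF_1"
    spur <- is.na(reason) &
      (candidates$units < 2 |
         !vapply(seq_len(n), function(i)
           motif_matches_locus(candidates$motif[i], candidates$sequence[i]),
           logical(1)))
    reason[spur] <- "SPURIOUS"
    # duplicates: identical span, different parameters; keep best fit
    key <- paste(candidates$seqid, candidates$start, candidates$end, sep = "\r")
    for (idx in split(which(is.na(reason)), key[is.na(reason)])) {
      if (length(idx) <= 1L) next
      span <- candidates$end[idx[1]] - candidates$start[idx[1]]
      fit <- abs(nchar(candidates$motif[idx]) * candidates$units[idx] - span)
      keep <- idx[order(fit, nchar(candidates$motif[idx]))][1]
      reason[setdiff(idx, keep)] <- "DUPLICATE"
    }
  }
  rejected <- candidates[!is.na(reason), , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!is.na(reason)]
  else rejected$reason <- character()
  list(kept = candidates[is.na(reason), , drop = FALSE], rejected = rejected)
}

# Does the motif, tiled over the locus in its best phase, match at
# least half the positions?
motif_matches_locus <- function(motif, locus) {
  if (is.na(locus) || !nzchar(locus)) return(FALSE)
  p <- nchar(motif)
  L <- nchar(locus)
  if (p == 0L || p > L) return(FALSE)
  x <- utf8ToInt(locus)
  m <- utf8ToInt(motif)
  best <- 0
  for (phase in seq_len(p) - 1L) {
    tiled <- m[((seq_len(L) - 1L + phase) %% p) + 1L]
    best <- max(best, mean(x == tiled))
  }
  best >= 0.5
}

#' Write a rejection audit TSV
#'
#' @param rejected The `rejected` element of
#'   [apply_low_quality_filters()].
#' @param path Output path.
#' @export
write_rejection_audit <- function(rejected, path) {
  cols <- intersect(c("seqid", "start", "end", "motif", "units", "reason"),
                    names(rejected))
  utils::write.table(rejected[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
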