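#' Consensus motif of equal-length repeat units
#'
#' Per-position majority base; ties resolve to the base of the first
#' unit.
#'
#' @param unit_strings Character vector of equal-length units.
#' @return The consensus string.
#' @examples
#' consensus_motif(c("ATT", "ATT", "ATC"))
#' @export
consensus_motif <- function(unit_strings) {
  if (length(unit_strings) == 0L) stop("need at least one unit")
  p <- unique(nchar(unit_strings))
  if (length(p) != 1L) stop("units must have equal length")
  m <- matrix(unlist(strsplit(unit_strings, "", fixed = TRUE)),
              nrow = p, byrow = FALSE)
  out <- vapply(seq_len(p), function(i) {
    tab <- table(m[i, ])
    best <- names(tab)[tab == max(tab)]
    if (length(best) == 1L) best else m[i, 1L]  # tie -> first unit's base
  }, character(1))
  paste(out, collapse = "")
}

# Core scanner on an integer-coded sequence. Seeds are exact adjacent
# doublets (smallest period at the leftmost position wins); extension
# proceeds unit by unit in scan direction, charging Hamming mismatches
# against the seed motif. The reported repeat is the unit prefix that
# maximizes a per-base alignment score (+1 match, -2 mismatch; ties go
# to the longest prefix, so degenerate units at a repeat's end are
# kept), additionally subject to the global mismatch budget
# floor(max_mismatch_fraction * span) evaluated at that prefix (or an
# absolute `max_mismatches` when given). The score objective keeps
# extension from drifting into unrelated sequence no matter how much
# budget a long pure repeat has accrued; the scan ahead also stops
# after 3 consecutive units that each mismatch in at least half their
# positions, and such units are trimmed from the reported end.
detect_core <- function(x_int, min_motif, max_motif, min_units,
                        max_mismatch_fraction, max_mismatches) {
  L <- length(x_int)
  out <- list()
  max_p <- min(max_motif, L %/% 2L)
  if (max_p < min_motif) return(out)
  seedp <- rep(NA_integer_, L)
  for (p in seq(max_p, min_motif)) {  # descending: smallest p overwrites
    eq <- x_int[seq_len(L - p)] == x_int[seq.int(1L + p, L)]
    npos <- L - 2L * p + 1L
    if (npos < 1L) next
    cs <- c(0L, cumsum(eq))
    ok <- (cs[seq_len(npos) + p] - cs[seq_len(npos)]) == p
    seedp[which(ok)] <- p
  }
  i <- 1L
  lim <- L - 2L * min_motif + 1L
  while (i <= lim) {
    p <- seedp[i]
    if (is.na(p)) { i <- i + 1L; next }
    K <- (L - i + 1L) %/% p
    motif0 <- x_int[i:(i + p - 1L)]
    mm <- colSums(matrix(x_int[i:(i + K * p - 1L)], nrow = p) != motif0)
    half <- ceiling(p / 2)
    high <- mm >= half
    run3 <- if (K >= 3L)
      which(high[3:K] & high[2:(K - 1L)] & high[1:(K - 2L)]) + 2L else integer()
    stop_at <- if (length(run3)) run3[1] else K
    cum <- cumsum(mm[seq_len(stop_at)])
    limit <- if (!is.null(max_mismatches)) max_mismatches else
      floor(max_mismatch_fraction * p * seq_len(stop_at))
    score <- cumsum(p - 3L * mm[seq_len(stop_at)])  # +1 match, -2 mismatch
    valid <- which(cum <= limit)
    u <- if (length(valid)) {
      best <- valid[score[valid] == max(score[valid])]
      best[length(best)]  # tie -> longest prefix
    } else 0L
    while (u > 0L && high[u]) u <- u - 1L  # trim ragged end units
    # extend backward over whole units (a mutated leading unit breaks
    # the seed doublet but not the repeat), same scoring and budget
    ub <- 0L
    if (u >= min_units) {
      Kb <- (i - 1L) %/% p
      if (Kb > 0L) {
        mmb <- vapply(seq_len(Kb), function(j)
          sum(x_int[(i - j * p):(i - (j - 1L) * p - 1L)] != motif0),
          numeric(1))
        highb <- mmb >= half
        run3b <- if (Kb >= 3L)
          which(highb[3:Kb] & highb[2:(Kb - 1L)] & highb[1:(Kb - 2L)]) + 2L else
          integer()
        stop_b <- if (length(run3b)) run3b[1] else Kb
        cumb <- cumsum(mmb[seq_len(stop_b)])
        limitb <- if (!is.null(max_mismatches)) max_mismatches - cum[u] else
          floor(max_mismatch_fraction * p * (u + seq_len(stop_b))) - cum[u]
        scoreb <- cumsum(p - 3L * mmb[seq_len(stop_b)])
        validb <- which(cumb <= limitb)
        if (length(validb) && max(scoreb[validb]) > 0L) {
          # backward ties go to the shortest: only units that strictly
          # improve the score are pulled in
          bestb <- validb[scoreb[validb] == max(scoreb[validb])]
          ub <- bestb[1]
        }
        while (ub > 0L && highb[ub]) ub <- ub - 1L
      }
    }
    if (u + ub >= min_units && u >= 2L) {
      out[[length(out) + 1L]] <- c(start = i - 1L - ub * p,
                                   end = i - 1L + u * p,
                                   period = p, units = u + ub)
      i <- i + u * p
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Detect tandem repeats with a mismatch-tolerant seed-and-extend scan
#'
#' Seeds are exact motif doublets; extension charges Hamming mismatches
#' against the seed motif under a global per-repeat budget. Because the
#' seed is the first doublet met in scan order, scanning direction can
#' change the output: a repeat whose first units are degenerate in one
#' direction may be reported with fewer units when scanned the other
#' way.
#'
#' @param sequence Nucleotide string.
#' @param min_motif,max_motif Motif length range scanned (default 2-100).
#' @param min_units Minimum reported unit count (default 3).
#' @param max_mismatch_fraction Mismatch budget as a fraction of the
#'   reported repeat span (default 0.15).
#' @param max_mismatches Optional absolute mismatch budget overriding
#'   the fraction.
#' @param direction `"left_to_right"` (default) or `"right_to_left"`.
#' @return Data frame with `start`, `end` (0-based half-open, always in
#'   the input orientation), `period`, `units`, `motif` (consensus),
#'   `mismatches` (vs the consensus) and `sequence` (the locus).
#' @export
detect_tandem_repeats <- function(sequence, min_motif = 2L, max_motif = 100L,
                                  min_units = 3L, max_mismatch_fraction = 0.15,
                                  max_mismatches = NULL,
                                  direction = c("left_to_right", "right_to_left")) {
  direction <- match.arg(direction)
  stopifnot(nzchar(sequence), min_motif >= 1L, min_motif <= max_motif,
            min_units >= 2L, max_mismatch_fraction >= 0,
            max_mismatch_fraction < 0.5)
  sequence <- toupper(sequence)
  scan_seq <- if (direction == "right_to_left") reverse_string(sequence) else sequence
  hits <- detect_core(utf8ToInt(scan_seq), as.integer(min_motif),
                      as.integer(max_motif), as.integer(min_units),
                      max_mismatch_fraction, max_mismatches)
  L <- nchar(sequence)
  rows <- lapply(hits, function(h) {
    s <- h[["start"]]; e <- h[["end"]]; p <- h[["period"]]; u <- h[["units"]]
    if (direction == "right_to_left") { tmp <- s; s <- L - e; e <- L - tmp }
    locus <- substr(sequence, s + 1L, e)
    units <- substring(locus, seq(1L, u * p, by = p), seq(p, u * p, by = p))
    cons <- consensus_motif(units)
    mmc <- sum(vapply(units, function(x)
      sum(utf8ToInt(x) != utf8ToInt(cons)), integer(1)))
    data.frame(start = s, end = e, period = p, units = u, motif = cons,
               mismatches = mmc, sequence = locus, stringsAsFactors = FALSE)
  })
  if (length(rows) == 0L)
    return(data.frame(start = integer(), end = integer(), period = integer(),
                      units = integer(), motif = character(),
                      mismatches = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$start), , drop = FALSE]
}

#' Convert detector output to TR candidates
#'
#' Detection coordinates are mapped back to the forward genomic frame:
#' for a minus-strand region the scanned sequence was the reverse
#' complement, so coordinates are flipped within the region.
#'
#' @param detections Data frame from [detect_tandem_repeats()].
#' @param seqid Sequence id of the scanned sequence.
#' @param strand Strand of the scanned region.
#' @param offset 0-based forward-frame offset of the region on `seqid`.
#' @param tool Tool label recorded in `tools`.
#' @param region_length Length of the scanned region; required to flip
#'   minus-strand coordinates.
#' @return Candidate data frame.
#' @export
detections_to_candidates <- function(detections, seqid, strand = "+",
                                     offset = 0L, tool = "ptrcensus",
                                     region_length = NULL) {
  if (nrow(detections) == 0L) return(empty_candidates())
  start <- detections$start
  end <- detections$end
  if (strand == "-") {
    if (is.null(region_length))
      stop("region_length is required for minus-strand regions")
    tmp <- start
    start <- region_length - end
    end <- region_length - tmp
  }
  data.frame(seqid = seqid, start = start + as.integer(offset),
             end = end + as.integer(offset), strand = strand,
             motif = detections$motif, units = as.numeric(detections$units),
             sequence = detections$sequence, tools = tool,
             stringsAsFactors = FALSE)
}
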