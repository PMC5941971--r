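#' Extract the flanking regions of a reference TR
#'
#' The two 250 bp regions immediately upstream and downstream of the
#' repeat anchor it in a target assembly: the repeat itself is too
#' repetitive to place uniquely, its flanks usually are not. Flanks are
#' clamped (and flagged) when the repeat sits near a sequence end.
#'
#' Flanks are reported 5' to 3' on the candidate's strand: for a
#' minus-strand repeat, `left` is the reverse complement of the
#' downstream genomic flank (and placement then expects target images
#' in the same orientation).
#'
#' @param tr One candidate (list or one-row data frame with `seqid`,
#'   `start`, `end`, `strand`).
#' @param genome Named character vector holding the reference sequence.
#' @param flank_bp Flank size (default 250).
#' @return List with `left`, `right` (nucleotide strings),
#'   `clipped_left`, `clipped_right` flags.
#' @export
extract_flanks <- function(tr, genome, flank_bp = 250L) {
  s <- genome[[as.character(tr$seqid)]]
  if (is.null(s)) stop("unknown sequence: ", tr$seqid)
  L <- nchar(s)
  ls <- max(0L, tr$start - flank_bp)
  re <- min(L, tr$end + flank_bp)
  upstream <- substr(s, ls + 1L, tr$start)
  downstream <- substr(s, tr$end + 1L, re)
  minus <- !is.null(tr$strand) && as.character(tr$strand) == "-"
  rc <- function(x) if (nzchar(x))
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x))) else x
  list(left = if (minus) rc(downstream) else upstream,
       right = if (minus) rc(upstream) else downstream,
       clipped_left = if (minus) (re - tr$end) < flank_bp else (tr$start - ls) < flank_bp,
       clipped_right = if (minus) (tr$start - ls) < flank_bp else (re - tr$end) < flank_bp)
}

#' Local alignment of a query against a subject, all near-best hits
#'
#' Smith-Waterman semantics with linear gaps and +1/-1/-1 weights.
#' Secondary hits are recovered by masking the subject span of each
#' reported hit and re-aligning, so multi-mapping flanks surface as
#' several rows.
#'
#' @param query Query string (at least 20 bp).
#' @param subject Subject string.
#' @param max_hits Maximum number of hits returned (default 8).
#' @param rel_floor Stop collecting hits whose score falls below this
#'   fraction of the best score (default 0.75).
#' @return Data frame of hits sorted by score (descending): `score`,
#'   `matches`, `aln_len`, `identity_pct`, `query_start`, `query_end`,
#'   `subject_start`, `subject_end` (0-based half-open).
#' @export
local_align <- function(query, subject, max_hits = 8L, rel_floor = 0.75) {
  if (nchar(query) < 20L) stop("query must be at least 20 bp")
  sw_hits_cpp(query, subject, as.integer(max_hits), rel_floor)
}

#' Place a flank pair on a target sequence
#'
#' Both flanks must align uniquely, in order, at >= 90% identity, with
#' at least 450 of their 500 bases matched (thresholds scale when a
#' flank was clipped at a sequence end). Every failure mode is returned
#' as a typed status rather than an error: `ONE_FLANK_ONLY` (one flank
#' has no qualifying hit), `LOW_IDENTITY` (neither does),
#' `MULTI_MAPPED` (a flank has several near-tied qualifying hits),
#' `WRONG_ORDER` (right flank before left), `COMBINED_BELOW_450`
#' (combined matches under threshold) or `PLACED`.
#'
#' The enclosed segment is taken between the flanks after projecting
#' each chosen hit to its full query extent, so a terminal flank SNP
#' trimmed by the local alignment does not leak flank bases into the
#' segment. A zero-length segment is a legal placement: it means the
#' repeat was lost entirely in the target.
#'
#' @param flanks A flank pair from [extract_flanks()].
#' @param target_sequence The target gene image (already extended).
#' @param min_identity_pct Minimum per-flank identity (default 90).
#' @param min_match_frac Combined matched fraction of flank bases
#'   (default 0.9, i.e. 450/500 for two full flanks).
#' @param near_tie Secondary hits within this fraction of the best
#'   score count as alternative mappings (default 0.05).
#' @param max_hits Passed to [local_align()].
#' @return List with `status`, and when `PLACED`: `target_start`,
#'   `target_end`, `target_sequence`, `identity_left`, `identity_right`,
#'   `matches_total`.
#' @export
place_flanks <- function(flanks, target_sequence, min_identity_pct = 90,
                         min_match_frac = 0.9, near_tie = 0.05,
                         max_hits = 8L) {
  nl <- nchar(flanks$left); nr <- nchar(flanks$right)
  res <- list(status = NA_character_, target_start = NA_integer_,
              target_end = NA_integer_, target_sequence = NA_character_,
              identity_left = NA_real_, identity_right = NA_real_,
              matches_total = NA_integer_)
  qual <- function(fl) {
    if (nchar(fl) < 20L)
      return(data.frame())
    h <- local_align(fl, target_sequence, max_hits = max_hits)
    h[h$identity_pct >= min_identity_pct, , drop = FALSE]
  }
  ql <- qual(flanks$left); qr <- qual(flanks$right)
  if (nrow(ql) == 0L && nrow(qr) == 0L) { res$status <- "LOW_IDENTITY"; return(res) }
  if (nrow(ql) == 0L || nrow(qr) == 0L) { res$status <- "ONE_FLANK_ONLY"; return(res) }
  multi <- function(h) sum(h$score >= (1 - near_tie) * h$score[1]) > 1L
  if (multi(ql) || multi(qr)) { res$status <- "MULTI_MAPPED"; return(res) }
  l <- ql[1, ]; r <- qr[1, ]
  if (r$subject_start < l$subject_start) { res$status <- "WRONG_ORDER"; return(res) }
  matches_total <- l$matches + r$matches
  if (matches_total < min_match_frac * (nl + nr)) {
    res$status <- "COMBINED_BELOW_450"
    res$matches_total <- matches_total
    return(res)
  }
  # project hits to the full flank extent before taking the segment
  seg_start <- l$subject_end + (nl - l$query_end)
  seg_end <- r$subject_start - r$query_start
  seg_start <- min(seg_start, nchar(target_sequence))
  if (seg_end < seg_start) seg_end <- seg_start  # flanks (over)lap: lost TR
  res$status <- "PLACED"
  res$target_start <- as.integer(seg_start)
  res$target_end <- as.integer(seg_end)
  res$target_sequence <- substr(target_sequence, seg_start + 1L, seg_end)
  res$identity_left <- l$identity_pct
  res$identity_right <- r$identity_pct
  res$matches_total <- as.integer(matches_total)
  res
}
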