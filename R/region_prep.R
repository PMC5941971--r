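#' Merge overlapping transcripts into scanned regions
#'
#' Transcripts of the same gene (isoforms) overlap heavily; scanning
#' each isoform separately would detect the same repeats many times, so
#' overlapping transcripts are merged per sequence and per strand before
#' detection. Opposite-strand overlaps are kept separate because
#' seed-and-extend detectors are direction sensitive. Touching
#' (bookended) intervals are not merged: only a shared base counts as
#' overlap.
#'
#' @param transcripts Data frame with `transcript_id`, `seqid`, `start`,
#'   `end`, `strand` (0-based half-open); `gene_id` optional.
#' @return Data frame of merged regions (`seqid`, `start`, `end`,
#'   `strand`) with a `members` list column of transcript ids.
#' @export
merge_transcripts <- function(transcripts) {
  if (is.null(transcripts) || nrow(transcripts) == 0L) {
    out <- data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  gr <- as_granges0(transcripts)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  out <- granges_to_df0(red)
  ids <- if ("transcript_id" %in% names(transcripts))
    transcripts$transcript_id else as.character(seq_len(nrow(transcripts)))
  out$members <- lapply(S4Vectors::mcols(red)$revmap, function(i) ids[i])
  out <- out[order(out$seqid, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the sequence of an interval from a genome
#'
#' Minus-strand intervals return the reverse complement, so the result
#' always reads 5' to 3' on the annotated strand.
#'
#' @param genome Named character vector of sequences.
#' @param interval One interval (`seqid`, `start`, `end`, `strand`).
#' @return Nucleotide string of length `end - start`.
#' @export
extract_sequence <- function(genome, interval) {
  seqid <- as.character(interval$seqid)
  if (!seqid %in% names(genome)) stop("unknown sequence: ", seqid)
  s <- genome[[seqid]]
  if (interval$start < 0L || interval$end > nchar(s))
    stop("interval [", interval$start, ",", interval$end,
         ") out of bounds for ", seqid, " (length ", nchar(s), ")")
  sub <- substr(s, interval$start + 1L, interval$end)
  if (!is.null(interval$strand) && as.character(interval$strand) == "-")
    sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  sub
}

#' Build the scanned sequence set from transcripts
#'
#' Merges transcripts, extends each merged region (default 1,000 bp on
#' both sides, clamped to the sequence), and extracts the region
#' sequences.
#'
#' @param transcripts Transcript data frame (see [merge_transcripts()]).
#' @param genome Named character vector of reference sequences.
#' @param pad_bp Extension applied to each merged region (default 1000).
#' @return The merged-region data frame with extended coordinates and a
#'   `sequence` column.
#' @export
prepare_regions <- function(transcripts, genome, pad_bp = 1000L) {
  regions <- merge_transcripts(transcripts)
  if (nrow(regions) == 0L) {
    regions$sequence <- character()
    return(regions)
  }
  for (i in seq_len(nrow(regions))) {
    ext <- extend_interval(regions[i, c("seqid", "start", "end", "strand")],
                           pad_bp, nchar(genome[[regions$seqid[i]]]))
    regions$start[i] <- ext$start
    regions$end[i] <- ext$end
  }
  regions$sequence <- vapply(seq_len(nrow(regions)), function(i)
    extract_sequence(genome, regions[i, ]), character(1))
  regions
}
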