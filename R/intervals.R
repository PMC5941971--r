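#' Genomic interval records
#'
#' Intervals are plain data frames with columns `seqid`, `start`, `end`
#' and `strand`, 0-based half-open (`start` inclusive, `end` exclusive).
#' Conversion to 1-based inclusive coordinates happens only at I/O
#' boundaries (catalog TSV, TRF `.dat`); BED import/export keeps the
#' native 0-based half-open convention.
#'
#' @param seqid Character vector of sequence identifiers.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand `"+"` or `"-"` (recycled).
#' @return A data frame with one row per interval.
#' @examples
#' gintervals("chr1", 10, 50)
#' @export
gintervals <- function(seqid, start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integral")
  if (any(start < 0L)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval must satisfy start < end")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(seqid = as.character(seqid), start = start, end = end,
             strand = as.character(strand), stringsAsFactors = FALSE)
}

#' Jaccard coefficient of two genomic intervals
#'
#' Intersection over union of the base positions covered by two
#' intervals. Intervals on different sequences share no bases, so their
#' coefficient is 0.
#'
#' @param a,b Single intervals: anything with `seqid`, `start`, `end`
#'   fields (one-row data frames or lists).
#' @return A number in `[0, 1]`; 1 exactly when the intervals are
#'   identical.
#' @examples
#' jaccard_coefficient(gintervals("c", 0, 10), gintervals("c", 5, 15))
#' @export
jaccard_coefficient <- function(a, b) {
  if (as.character(a$seqid) != as.character(b$seqid)) return(0)
  inter <- max(0L, min(a$end, b$end) - max(a$start, b$start))
  uni <- (a$end - a$start) + (b$end - b$start) - inter
  inter / uni
}

# Vectorised Jaccard of one interval against columns of a data frame.
jaccard_vec <- function(seqid, start, end, df) {
  inter <- pmax(0L, pmin(end, df$end) - pmax(start, df$start))
  uni <- (end - start) + (df$end - df$start) - inter
  j <- inter / uni
  j[df$seqid != seqid] <- 0
  j
}

#' Extend an interval symmetrically, clamped to the sequence
#'
#' Used for the 1,000 bp extension of merged genic regions before
#' repeat detection and for the 250 / 1,250 bp allowances applied to
#' target gene images before flank placement.
#'
#' @param interval One interval (list or one-row data frame with
#'   `start`, `end`).
#' @param pad_bp Non-negative pad applied on both sides.
#' @param sequence_length Length of the host sequence, for clamping.
#' @return The extended interval with the same `seqid`/`strand`.
#' @export
extend_interval <- function(interval, pad_bp, sequence_length) {
  if (pad_bp < 0) stop("pad_bp must be >= 0")
  out <- interval
  out$start <- max(0L, as.integer(interval$start - pad_bp))
  out$end <- min(as.integer(sequence_length), as.integer(interval$end + pad_bp))
  out
}

# data frame (0-based half-open) -> GRanges (1-based inclusive)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*")
}

granges_to_df0 <- function(gr) {
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
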