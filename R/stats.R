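#' Match two catalogs by interval Jaccard coefficient
#'
#' Each source item counts as *overlap* when at least one target item
#' exceeds the Jaccard threshold `j` (`>= j` at `j = 1`, where strict
#' exceedance is impossible). The comparison is asymmetric: swap the
#' arguments to count the other direction.
#'
#' @param source,target Catalogs (`ptr_catalog`) or interval data
#'   frames (`seqid`, `start`, `end`).
#' @param j Jaccard threshold in `(0, 1]`.
#' @return Named integer vector `c(overlap =, no_overlap =)` summing to
#'   the number of source items.
#' @export
match_catalogs <- function(source, target, j) {
  stopifnot(j > 0, j <= 1)
  src <- if (inherits(source, "ptr_catalog")) as.data.frame(source) else source
  tgt <- if (inherits(target, "ptr_catalog")) as.data.frame(target) else target
  if (nrow(src) == 0L) return(c(overlap = 0L, no_overlap = 0L))
  if (nrow(tgt) == 0L)
    return(c(overlap = 0L, no_overlap = nrow(src)))
  hits <- GenomicRanges::findOverlaps(as_granges0(src), as_granges0(tgt),
                                      ignore.strand = TRUE)
  ov <- rep(FALSE, nrow(src))
  qi <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
  for (h in seq_along(qi)) {
    if (ov[qi[h]]) next
    jc <- jaccard_coefficient(src[qi[h], ], tgt[ti[h], ])
    if (if (j == 1) jc >= j else jc > j) ov[qi[h]] <- TRUE
  }
  c(overlap = sum(ov), no_overlap = sum(!ov))
}

#' Stratified PTR/TR ratio with bootstrap confidence intervals
#'
#' The fraction of candidate repeats certified polymorphic, stratified
#' by motif-size class and by repeat-unit class, each with a
#' percentile-bootstrap 95% confidence interval over resampled loci.
#'
#' @param candidates Candidate data frame (the TR denominator).
#' @param catalog A `ptr_catalog` (the PTR numerator); candidates are
#'   matched to records by identical reference interval and motif.
#' @param motif_breaks,unit_breaks Break vectors for
#'   [base::cut()]-style stratification (right-open). Defaults: motif
#'   sizes 2-6 singly then 7+, unit classes 2,5,10,20,40+.
#' @param n_boot Bootstrap replicates (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return Data frame: `motif_class`, `unit_class`, `n_tr`, `n_ptr`,
#'   `ratio`, `ci_lo`, `ci_hi`; strata with no candidates are omitted.
#' @export
ptr_tr_ratio <- function(candidates, catalog,
                         motif_breaks = c(2, 3, 4, 5, 6, 7, Inf),
                         unit_breaks = c(2, 5, 10, 20, 40, Inf),
                         n_boot = 200L, seed = 1L) {
  stopifnot(n_boot >= 100L)
  cat_df <- as.data.frame(catalog)
  cat_key <- paste(cat_df$seqid, cat_df$start, cat_df$end, cat_df$motif)
  is_ptr <- paste(candidates$seqid, candidates$start, candidates$end,
                  candidates$motif) %in% cat_key
  motif_class <- cut(nchar(candidates$motif), motif_breaks, right = FALSE,
                     include.lowest = TRUE)
  unit_class <- cut(round_half_away(candidates$units), unit_breaks,
                    right = FALSE, include.lowest = TRUE)
  strata <- split(seq_len(nrow(candidates)),
                  list(motif = motif_class, units = unit_class), drop = TRUE)
  withr::with_seed(seed, {
    rows <- lapply(names(strata), function(nm) {
      idx <- strata[[nm]]
      flags <- is_ptr[idx]
      ratio <- mean(flags)
      boot <- replicate(n_boot, mean(sample(flags, replace = TRUE)))
      ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
      cls <- strsplit(nm, ".", fixed = TRUE)[[1]]
      data.frame(motif_class = cls[1], unit_class = cls[2],
                 n_tr = length(idx), n_ptr = sum(flags), ratio = ratio,
                 ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, rows)
}

#' Histogram of unit differences across the catalog
#'
#' @param catalog A `ptr_catalog`.
#' @return Named integer vector: counts per signed delta (names like
#'   `"+1"`, `"-2"`), sorted by delta. Delta 0 never occurs (gated at
#'   catalog assembly).
#' @export
delta_histogram <- function(catalog) {
  df <- as.data.frame(catalog)
  if (nrow(df) == 0L) return(stats::setNames(integer(), character()))
  tab <- table(df$delta_units)
  d <- as.integer(names(tab))
  ord <- order(d)
  stats::setNames(as.integer(tab)[ord], sprintf("%+d", d[ord]))
}

#' Windowed Spearman correlation of repeat-unit counts and SNP density
#'
#' Tiles the analyzed regions with non-overlapping windows (left
#' aligned, partial trailing windows dropped), computes the mean
#' reference repeat-unit count of the catalog records starting in each
#' window and the number of SNPs falling in it, and correlates the two
#' over windows containing at least one record. Ties get average
#' ranks; the p-value uses the large-sample t approximation.
#'
#' @param catalog A `ptr_catalog`.
#' @param snp_positions Data frame with `seqid` and `pos` (0-based) or
#'   `start` columns.
#' @param window_bp Window size in bp (5,000-50,000 in the intended
#'   range).
#' @param regions Optional interval data frame to tile; default: the
#'   span of the catalog records per sequence.
#' @return List: `rho`, `p_value`, `n_windows`.
#' @export
snp_density_correlation <- function(catalog, snp_positions, window_bp,
                                    regions = NULL) {
  df <- as.data.frame(catalog)
  pos <- if ("pos" %in% names(snp_positions)) snp_positions$pos else
    snp_positions$start
  snp_seq <- snp_positions$seqid
  if (is.null(regions)) {
    regions <- do.call(rbind, lapply(split(df, df$seqid), function(g)
      data.frame(seqid = g$seqid[1], start = min(g$start),
                 end = max(g$end), stringsAsFactors = FALSE)))
  }
  units_mean <- numeric(); snp_count <- integer()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    n_win <- (r$end - r$start) %/% window_bp
    if (n_win < 1L) next
    for (w in seq_len(n_win)) {
      ws <- r$start + (w - 1L) * window_bp
      we <- ws + window_bp
      in_win <- df$seqid == r$seqid & df$start >= ws & df$start < we
      if (!any(in_win)) next
      units_mean <- c(units_mean, mean(df$units[in_win]))
      snp_count <- c(snp_count, sum(snp_seq == r$seqid & pos >= ws & pos < we))
    }
  }
  if (length(units_mean) < 3L)
    stop("fewer than 3 non-empty windows: correlation undefined")
  n <- length(units_mean)
  rho <- stats::cor(rank(units_mean), rank(snp_count))
  p <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n_windows = n)
}
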