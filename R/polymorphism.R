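#' Evolutionary (Sellers) distance with leftmost truncation
#'
#' A generalization of the Hamming distance: unit-cost minimum edit
#' distance (substitutions, insertions, deletions) computed with a
#' Needleman-Wunsch-style dynamic program. Strings of unequal length
#' are aligned on their leftmost symbol and the longer one is truncated
#' to the length of the shorter before the distance is computed.
#'
#' @param a,b Non-empty strings.
#' @return Integer distance in `[0, L]`, `L` the shorter length.
#' @examples
#' evolutionary_distance("ATTATTATCATCATTATTATC", strrep("ATT", 7))
#' @export
evolutionary_distance <- function(a, b) {
  nw_distance_cpp(a, b)
}

#' Test thresholds for the polymorphism checks
#'
#' `k = floor(0.1 n)` and `k' = floor(0.1 min(n, m - n - 1))` with `n`
#' the shorter and `m` the longer length: a tenth of the shorter
#' sequence for the prefix test, and of the smaller of shorter sequence
#' and residual for the residual test.
#'
#' @param n Length of the shorter sequence.
#' @param m Length of the longer sequence.
#' @return List with `k` and `k_prime`.
#' @export
test_thresholds <- function(n, m) {
  stopifnot(n >= 1L, m >= n)
  list(k = floor(0.1 * n), k_prime = floor(0.1 * max(0L, min(n, m - n - 1L))))
}

#' Test 1: is the shorter repeat a prefix of the longer?
#'
#' Requires `H(S, T[1..n]) <= k`, i.e. the shorter sequence and the
#' same-length prefix of the longer differ by at most `k` edits.
#'
#' @param S Shorter sequence.
#' @param T_ Longer sequence (`|T_| >= |S|`).
#' @param thresholds From [test_thresholds()]; recomputed when `NULL`.
#' @return Logical.
#' @export
test1 <- function(S, T_, thresholds = NULL) {
  n <- nchar(S)
  stopifnot(nchar(T_) >= n)
  if (is.null(thresholds)) thresholds <- test_thresholds(n, nchar(T_))
  evolutionary_distance(S, substr(T_, 1L, n)) <= thresholds$k
}

#' Test 2: does the residual continue the same motif?
#'
#' Requires `H(S, T[n+1..m]) <= k'`: the residual of the longer
#' sequence past the shared prefix must still read like the repeat
#' (the truncation rule of `H` compares the leading
#' `min(n, m - n)` bases). Vacuously true when there is no residual.
#'
#' @inheritParams test1
#' @return Logical.
#' @export
test2 <- function(S, T_, thresholds = NULL) {
  n <- nchar(S); m <- nchar(T_)
  stopifnot(m >= n)
  if (m == n) return(TRUE)
  if (is.null(thresholds)) thresholds <- test_thresholds(n, m)
  evolutionary_distance(S, substr(T_, n + 1L, m)) <= thresholds$k_prime
}

#' Estimate the repeat-unit count of the longer sequence
#'
#' The rounded ratio of the total matches in the two alignments to the
#' average motif size; rounding is half away from zero.
#'
#' @param matches_aln1,matches_aln2 Match counts of the prefix and
#'   residual alignments.
#' @param motif_size Average motif size of the reference repeat (may be
#'   fractional; must be >= 2).
#' @return Integer unit count.
#' @examples
#' estimate_target_units(30, 6, 3)  # 12
#' @export
estimate_target_units <- function(matches_aln1, matches_aln2, motif_size) {
  if (motif_size < 2) stop("motif_size must be >= 2 (single-base motifs are filtered)")
  as.integer(round_half_away((matches_aln1 + matches_aln2) / motif_size))
}

# The two alignment views used by the measurement: S vs the prefix
# T[1..n] and S vs the residual T[n+1..m]. For the residual view S is
# tiled periodically to at least the residual length, so expansions
# larger than the reference repeat itself still have all their matches
# counted; the reported query span is folded back onto S. Subject
# coordinates of the residual view are global on T.
tr_alignment_pair <- function(S, T_) {
  n <- nchar(S); m <- nchar(T_)
  a1v <- sw_best_cpp(S, substr(T_, 1L, n))
  aln1 <- list(matches = a1v[["matches"]], score = a1v[["score"]],
               query_span = c(a1v[["query_start"]], a1v[["query_end"]]),
               subject_span = c(a1v[["subject_start"]], a1v[["subject_end"]]))
  if (m == n) {
    aln2 <- list(matches = 0L, score = 0L, query_span = c(0L, 0L),
                 subject_span = c(n, n))
    return(list(aln1 = aln1, aln2 = aln2))
  }
  resid <- substr(T_, n + 1L, m)
  S_tiled <- if (m - n > n)
    substr(strrep(S, ceiling((m - n) / n)), 1L, m - n) else S
  a2v <- sw_best_cpp(S_tiled, resid)
  qs <- a2v[["query_start"]] %% n
  qe <- min(qs + (a2v[["query_end"]] - a2v[["query_start"]]), n)
  aln2 <- list(matches = a2v[["matches"]], score = a2v[["score"]],
               query_span = c(qs, qe),
               subject_span = c(n + a2v[["subject_start"]],
                                n + a2v[["subject_end"]]))
  list(aln1 = aln1, aln2 = aln2)
}

#' Grade the mutual consistency of the two alignments (Test 3)
#'
#' Let `S1`/`S2` be the substrings of `S` matched in the two
#' alignments and `T1`/`T2` the corresponding substrings of `T`. When
#' `T1` and `T2` are adjacent and `S1` and `S2` overlap the measurement
#' is *high* quality; when `T1` and `T2` are separated by a small gap
#' (up to one motif by default) and `S1`/`S2` still overlap it is
#' *medium*; anything else -- in particular disjoint `S1`/`S2` -- is
#' *low*. For small motifs (<= 4 bp) with a residual shorter than 8 bp
#' (an expansion or contraction below two units), medium additionally
#' requires the residual alignment to match more than half of the
#' shorter of its two strings.
#'
#' @param aln1,aln2 Alignment views from the prefix and residual
#'   alignments: lists with `matches`, `query_span`, `subject_span`
#'   (residual subject span global on `T`).
#' @param motif_size Motif size of the reference repeat.
#' @param shorter_len Length `n` of the shorter sequence.
#' @param residual_len Length `m - n` of the residual.
#' @param small_gap Maximum `T1`-`T2` gap still graded medium
#'   (default: one motif).
#' @return `"high"`, `"medium"` or `"low"`.
#' @export
classify_quality <- function(aln1, aln2, motif_size, shorter_len,
                             residual_len, small_gap = NULL) {
  if (is.null(small_gap)) small_gap <- ceiling(motif_size)
  if (residual_len == 0L) return("high")
  gap_t <- aln2$subject_span[1] - aln1$subject_span[2]
  s_overlap <- aln2$query_span[1] < aln1$query_span[2] &&
    aln1$query_span[1] < aln2$query_span[2]
  if (!s_overlap) return("low")
  if (gap_t == 0L) return("high")
  if (gap_t < 0L || gap_t > small_gap) return("low")
  if (motif_size <= 4 && residual_len < 8L &&
      aln2$matches <= 0.5 * min(shorter_len, residual_len)) return("low")
  "medium"
}

#' Measure the polymorphism of one reference repeat at one placement
#'
#' Orients the (reference, target) pair so the shorter sequence plays
#' `S`, runs Tests 1 and 2 with thresholds `k`, `k'`, estimates the
#' target unit count from the match counts of the two alignments, and
#' grades the measurement. A failed test forces quality `"low"`. The
#' delta sign is positive for target expansion, negative for
#' contraction; equal-length pairs are delta 0 (substitution-only
#' variation is not a repeat polymorphism). An empty target segment is
#' a complete loss of the repeat: delta `-units_ref`.
#'
#' @param tr One candidate (needs `sequence`, `motif`, `units`).
#' @param placement A `PLACED` result of [place_flanks()].
#' @param genome Label of the target genome.
#' @param small_gap Passed to [classify_quality()].
#' @return List: `genome`, `delta_units`, `units_target`,
#'   `matches_aln1`, `matches_aln2`, `quality`, `test1`, `test2`, `k`,
#'   `k_prime`, `target_start`, `target_end`.
#' @export
measure_polymorphism <- function(tr, placement, genome = "target",
                                 small_gap = NULL) {
  if (!identical(placement$status, "PLACED"))
    stop("measure_polymorphism requires a PLACED placement")
  S0 <- toupper(tr$sequence)
  T0 <- toupper(placement$target_sequence)
  units_ref <- as.integer(round_half_away(tr$units))
  motif_size <- nchar(S0) / tr$units  # average motif size of S
  out <- list(genome = genome, delta_units = NA_integer_,
              units_target = NA_integer_, matches_aln1 = NA_integer_,
              matches_aln2 = NA_integer_, quality = "low",
              test1 = NA, test2 = NA, k = NA_integer_, k_prime = NA_integer_,
              target_start = placement$target_start,
              target_end = placement$target_end)
  if (!nzchar(T0)) {  # complete loss: flanks adjacent in the target
    out$delta_units <- -units_ref
    out$units_target <- 0L
    out$matches_aln1 <- 0L; out$matches_aln2 <- 0L
    out$quality <- "high"; out$test1 <- TRUE; out$test2 <- TRUE
    out$k <- 0L; out$k_prime <- 0L
    return(out)
  }
  target_longer <- nchar(T0) >= nchar(S0)
  S <- if (target_longer) S0 else T0
  T_ <- if (target_longer) T0 else S0
  n <- nchar(S); m <- nchar(T_)
  th <- test_thresholds(n, m)
  t1 <- test1(S, T_, th)
  t2 <- test2(S, T_, th)
  alns <- tr_alignment_pair(S, T_)
  m1 <- alns$aln1$matches; m2 <- alns$aln2$matches
  units_longer <- estimate_target_units(m1, m2, motif_size)
  units_shared <- as.integer(round_half_away(m1 / motif_size))
  units_target <- if (target_longer) units_longer else units_shared
  quality <- classify_quality(alns$aln1, alns$aln2, motif_size, n, m - n,
                              small_gap)
  if (!t1 || !t2) quality <- "low"
  out$delta_units <- units_target - units_ref
  out$units_target <- units_target
  out$matches_aln1 <- m1; out$matches_aln2 <- m2
  out$quality <- quality
  out$test1 <- t1; out$test2 <- t2
  out$k <- as.integer(th$k); out$k_prime <- as.integer(th$k_prime)
  out
}

#' Pick the representative measurement of a repeat
#'
#' Target locations are ranked by measurement quality (high > medium >
#' low), then by decreasing absolute unit difference, then by leftmost
#' target interval (then genome label) for determinism; the top-ranked
#' measurement is returned with the number of competing locations
#' attached.
#'
#' @param measurements Data frame of measurements (rows as returned by
#'   [measure_polymorphism()], rbind-ed) or a list of such lists.
#' @return The winning measurement as a list, with `n_locations`.
#' @export
select_best_measurement <- function(measurements) {
  if (is.list(measurements) && !is.data.frame(measurements))
    measurements <- do.call(rbind, lapply(measurements, function(x)
      as.data.frame(x[c("genome", "delta_units", "units_target",
                        "matches_aln1", "matches_aln2", "quality",
                        "target_start", "target_end")],
                    stringsAsFactors = FALSE)))
  if (nrow(measurements) == 0L) stop("no measurements to select from")
  ord <- order(-quality_rank(measurements$quality),
               -abs(measurements$delta_units),
               measurements$target_start, measurements$genome)
  best <- as.list(measurements[ord[1], ])
  best$n_locations <- nrow(measurements)
  best
}
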