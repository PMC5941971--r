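# Independent oracles and generators used across the suite.

# Unit-cost edit distance via base R's generalized Levenshtein,
# applied after the leftmost-truncation rule.
oracle_edit_distance <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  as.integer(utils::adist(substr(a, 1, L), substr(b, 1, L)))
}

# Brute-force edit-path enumeration (no memoization): explores every
# interleaving of substitutions, insertions and deletions. Only viable
# for short strings.
enum_edit_distance <- function(a, b) {
  L <- min(nchar(a), nchar(b))
  av <- strsplit(substr(a, 1, L), "")[[1]]
  bv <- strsplit(substr(b, 1, L), "")[[1]]
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    min(rec(i - 1L, j - 1L) + (av[i] != bv[j]),
        rec(i - 1L, j) + 1L,
        rec(i, j - 1L) + 1L)
  }
  rec(length(av), length(bv))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# A motif whose doubled form has no period shorter than its length, so
# a seed-and-extend scan anchored at the repeat start must pick the
# full motif length.
random_primitive_motif <- function(p) {
  repeat {
    m <- random_seq(p)
    if (p == 1L) return(m)
    rep2 <- strrep(m, 2)
    ok <- TRUE
    for (q in seq_len(p - 1L)) {
      if (substr(rep2, 1, q) == substr(rep2, q + 1, 2 * q)) { ok <- FALSE; break }
    }
    if (ok && substr(m, 1, 1) != substr(m, 2, 2)) return(m)
  }
}

# Plant exactly k substitutions at positions spaced apart, cycling
# each base to a fixed different one; spacing keeps the edit distance
# equal to the substitution count (verified by the caller).
plant_substitutions <- function(s, k, spacing = 3L, first = 1L) {
  pos <- seq(first, by = spacing, length.out = k)
  stopifnot(max(pos) <= nchar(s))
  map <- c(A = "C", C = "G", G = "T", T = "A")
  for (i in pos) substr(s, i, i) <- map[[substr(s, i, i)]]
  s
}

random_interval_set <- function(n, span = 1000L, max_len = 120L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(seqid = "chr", start = start, end = start + len, strand = "+",
             motif = replicate(n, random_seq(sample(2:8, 1))),
             units = sample(2:20, n, replace = TRUE),
             sequence = NA_character_, tools = "x",
             stringsAsFactors = FALSE)
}

# Naive fixed-point of the >50% overlap rule, written independently of
# the package implementation but with the same declared ordering
# (largest overlap fraction first, ties to the leftmost pair).
oracle_overlap_removal <- function(df, threshold = 0.5) {
  alive <- rep(TRUE, nrow(df))
  frac <- function(i, j) {
    ov <- max(0L, min(df$end[i], df$end[j]) - max(df$start[i], df$start[j]))
    ov / min(df$end[i] - df$start[i], df$end[j] - df$start[j])
  }
  repeat {
    idx <- which(alive)
    if (length(idx) < 2L) break
    pairs <- t(utils::combn(idx, 2L))
    fr <- apply(pairs, 1L, function(p) frac(p[1], p[2]))
    lm <- apply(pairs, 1L, function(p) min(df$start[p[1]], df$start[p[2]]))
    cand <- which(fr > threshold)
    if (length(cand) == 0L) break
    pick <- cand[order(-fr[cand], lm[cand])][1]
    i <- pairs[pick, 1]; j <- pairs[pick, 2]
    li <- df$end[i] - df$start[i]; lj <- df$end[j] - df$start[j]
    mi <- nchar(df$motif[i]); mj <- nchar(df$motif[j])
    drop <- if (li != lj) { if (li < lj) i else j
    } else if (mi != mj) { if (mi > mj) i else j
    } else { if (df$start[i] > df$start[j]) i else j }
    alive[drop] <- FALSE
  }
  df[alive, , drop = FALSE]
}

# Build a catalog whose records are the candidate rows flagged in
# `is_ptr`, each certified by one synthetic high-quality delta-+1
# measurement; used to exercise the statistics utilities on controlled
# inputs.
synthetic_catalog <- function(candidates, is_ptr, delta = NULL) {
  idx <- which(is_ptr)
  n <- length(idx)
  if (is.null(delta)) delta <- rep(1L, n)
  ms <- data.frame(candidate_id = idx, genome = rep("g1", n),
                   image = rep("img", n), status = rep("PLACED", n),
                   target_start = rep(0L, n),
                   target_end = candidates$end[idx] - candidates$start[idx],
                   delta_units = as.integer(delta),
                   units_target = as.integer(round(candidates$units[idx]) + delta),
                   matches_aln1 = rep(10L, n), matches_aln2 = rep(10L, n),
                   quality = rep("high", n), stringsAsFactors = FALSE)
  build_catalog(candidates, ms)
}

# One placement + measurement of a fixture through the real pipeline.
measure_fixture <- function(fx, ...) {
  cand <- fixture_candidate(fx)
  fl <- extract_flanks(cand, c(ref = fx$reference_sequence))
  pl <- place_flanks(fl, fx$target_sequence, ...)
  if (!identical(pl$status, "PLACED"))
    return(list(status = pl$status, measurement = NULL))
  list(status = "PLACED",
       measurement = measure_polymorphism(cand, pl, genome = "target"))
}
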