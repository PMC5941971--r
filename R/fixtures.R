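#' Specification of a synthetic reference/target fixture
#'
#' Describes one planted repeat polymorphism: a reference sequence
#' carrying a tandem repeat between two random flanks, and a target
#' variant of it where the repeat gained or lost `delta_units` units
#' and the flanks accumulated SNP/indel noise. The target repeat
#' inherits the (possibly mutated) reference units -- an expansion
#' appends pure motif copies, a contraction truncates -- mirroring how
#' copy-number change duplicates or deletes existing units.
#'
#' @param motif Motif string, or an integer length from which a random
#'   motif is drawn.
#' @param units_ref Reference unit count (>= 2).
#' @param delta_units Signed planted unit difference
#'   (`units_ref + delta_units >= 0`).
#' @param flank_bp Flank length on each side (default 400).
#' @param flank_snp_rate Per-base substitution rate in target flanks.
#' @param flank_indel_rate Per-base single-base indel rate in target
#'   flanks.
#' @param tr_unit_mutation_rate Per-unit probability that a reference
#'   repeat unit carries one substitution.
#' @param n_stretch Optional `c(position, length)`: plant a run of `N`
#'   in the reference repeat locus.
#' @param decoy If `TRUE`, a second copy of the left flank is embedded
#'   downstream in the target so the placement multi-maps.
#' @param seed Seed making the fixture reproducible.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(motif = "CAG", units_ref = 10L, delta_units = 2L,
                         flank_bp = 400L, flank_snp_rate = 0,
                         flank_indel_rate = 0, tr_unit_mutation_rate = 0,
                         n_stretch = NULL, decoy = FALSE, seed = 1L) {
  stopifnot(units_ref >= 2L, units_ref + delta_units >= 0L,
            flank_snp_rate >= 0, flank_snp_rate <= 0.2,
            flank_indel_rate >= 0, flank_indel_rate <= 0.2,
            tr_unit_mutation_rate >= 0, tr_unit_mutation_rate <= 0.2)
  structure(list(motif = motif, units_ref = as.integer(units_ref),
                 delta_units = as.integer(delta_units),
                 flank_bp = as.integer(flank_bp),
                 flank_snp_rate = flank_snp_rate,
                 flank_indel_rate = flank_indel_rate,
                 tr_unit_mutation_rate = tr_unit_mutation_rate,
                 n_stretch = n_stretch, decoy = isTRUE(decoy),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

mutate_flank <- function(s, snp_rate, indel_rate) {
  if (snp_rate > 0) {
    hit <- which(stats::runif(nchar(s)) < snp_rate)
    for (i in hit) s <- substitute_base(s, i)
  }
  if (indel_rate > 0) {
    hit <- which(stats::runif(nchar(s)) < indel_rate)
    for (i in rev(hit)) {  # right to left so positions stay valid
      if (stats::runif(1) < 0.5) {
        s <- paste0(substr(s, 1, i), sample(DNA_BASES, 1),
                    substr(s, i + 1, nchar(s)))
      } else {
        s <- paste0(substr(s, 1, i - 1), substr(s, i + 1, nchar(s)))
      }
    }
  }
  s
}

#' Generate a fixture with planted ground truth
#'
#' Deterministic under the spec's seed: the same spec always yields the
#' same sequences and intervals.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `fixture_truth`: `reference_sequence`,
#'   `target_sequence`, `tr_interval_ref`, `tr_interval_target`
#'   (0-based half-open `c(start, end)`), `planted_delta`, `motif`,
#'   `units_ref`, `units_target`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    motif <- if (is.character(spec$motif)) toupper(spec$motif) else
      random_dna(as.integer(spec$motif))
    p <- nchar(motif)
    units <- rep(motif, spec$units_ref)
    if (spec$tr_unit_mutation_rate > 0) {
      hit <- which(stats::runif(spec$units_ref) < spec$tr_unit_mutation_rate)
      for (i in hit) units[i] <- substitute_base(units[i], sample.int(p, 1L))
    }
    units_target_n <- spec$units_ref + spec$delta_units
    target_units <- if (spec$delta_units >= 0L)
      c(units, rep(motif, spec$delta_units)) else
      units[seq_len(units_target_n)]
    flank_l <- random_dna(spec$flank_bp)
    flank_r <- random_dna(spec$flank_bp)
    ref_tr <- paste(units, collapse = "")
    if (!is.null(spec$n_stretch)) {
      pos <- spec$n_stretch[1]; len <- spec$n_stretch[2]
      substr(ref_tr, pos + 1L, pos + len) <- strrep("N", len)
    }
    tgt_tr <- paste(target_units, collapse = "")
    tflank_l <- mutate_flank(flank_l, spec$flank_snp_rate, spec$flank_indel_rate)
    tflank_r <- mutate_flank(flank_r, spec$flank_snp_rate, spec$flank_indel_rate)
    target <- paste0(tflank_l, tgt_tr, tflank_r)
    if (spec$decoy) target <- paste0(target, flank_l)
    structure(list(
      reference_sequence = paste0(flank_l, ref_tr, flank_r),
      target_sequence = target,
      tr_interval_ref = c(spec$flank_bp, spec$flank_bp + nchar(ref_tr)),
      tr_interval_target = c(nchar(tflank_l), nchar(tflank_l) + nchar(tgt_tr)),
      planted_delta = spec$delta_units, motif = motif,
      units_ref = spec$units_ref, units_target = units_target_n,
      spec = spec), class = "fixture_truth")
  })
}

#' Generate a cohort of fixtures with parameters drawn from ranges
#'
#' Per-fixture parameters are sampled from the supplied vectors (a
#' length-1 value is fixed); per-fixture seeds are derived from the
#' cohort seed, so the cohort is reproducible end to end.
#'
#' @param n Number of fixtures.
#' @param spec_distribution Named list of candidate values for
#'   [fixture_spec()] arguments, e.g.
#'   `list(motif = 2:6, delta_units = c(-5:-1, 1:5))`.
#' @param seed Cohort seed.
#' @return List of `fixture_truth` objects.
#' @export
make_cohort <- function(n, spec_distribution = list(), seed = 1L) {
  stopifnot(n >= 1L)
  withr::with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
    draws <- lapply(seq_len(n), function(i)
      lapply(spec_distribution, function(v)
        if (length(v) > 1L) sample(v, 1L) else v))
  })
  lapply(seq_len(n), function(i) {
    args <- draws[[i]]
    args$seed <- sub_seeds[i]
    if (!is.null(args$units_ref) && !is.null(args$delta_units) &&
        args$units_ref + args$delta_units < 0L)
      args$delta_units <- -args$units_ref  # complete loss is the floor
    make_fixture(do.call(fixture_spec, args))
  })
}

#' Candidate row for a fixture's planted reference repeat
#'
#' Builds the TR candidate that a perfect detector would report for the
#' fixture, useful for exercising placement and measurement in
#' isolation from detection.
#'
#' @param fx A `fixture_truth`.
#' @param seqid Sequence id to use (default `"ref"`).
#' @return One-row candidate data frame.
#' @export
fixture_candidate <- function(fx, seqid = "ref") {
  data.frame(seqid = seqid, start = fx$tr_interval_ref[1],
             end = fx$tr_interval_ref[2], strand = "+", motif = fx$motif,
             units = as.numeric(fx$units_ref),
             sequence = substr(fx$reference_sequence,
                               fx$tr_interval_ref[1] + 1L,
                               fx$tr_interval_ref[2]),
             tools = "fixture", stringsAsFactors = FALSE)
}
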