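test_that("flanks are the 250 bp on each side, clamped and flagged at sequence ends", {
  withr::local_seed(31)
  g <- c(s = random_seq(1000))
  tr <- gintervals("s", 300, 330)
  fl <- extract_flanks(tr, g)
  expect_identical(fl$left, substr(g[["s"]], 51, 300))
  expect_identical(fl$right, substr(g[["s"]], 331, 580))
  expect_false(fl$clipped_left || fl$clipped_right)

  fl2 <- extract_flanks(gintervals("s", 100, 130), g)
  expect_equal(nchar(fl2$left), 100L)
  expect_true(fl2$clipped_left)
  expect_false(fl2$clipped_right)

  # purity: identical across calls
  expect_identical(extract_flanks(tr, g), extract_flanks(tr, g))
})

test_that("minus-strand flanks come back 5' to 3' on the repeat's strand", {
  withr::local_seed(32)
  g <- c(s = random_seq(800))
  tr <- gintervals("s", 300, 330, "-")
  fl <- extract_flanks(tr, g)
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_identical(fl$left, rc(substr(g[["s"]], 331, 580)))
  expect_identical(fl$right, rc(substr(g[["s"]], 51, 300)))
})

test_that("local_align reports exact hits, multiplicity, and planted divergence", {
  withr::local_seed(33)
  q <- random_seq(250)
  subject <- paste0(random_seq(300), q, random_seq(300))
  h <- local_align(q, subject)
  expect_equal(h$identity_pct[1], 100)
  expect_equal(h$matches[1], 250L)
  expect_equal(h$subject_start[1], 300L)
  expect_equal(h$subject_end[1], 550L)

  # the same query planted twice surfaces as two equal-scoring hits
  sub2 <- paste0(random_seq(100), q, random_seq(100), q, random_seq(100))
  h2 <- local_align(q, sub2)
  expect_gte(nrow(h2), 2L)
  expect_equal(h2$score[2], h2$score[1])

  # 30 substitutions spread over a 250 bp copy: identity 220/250 = 88%
  q_mut <- plant_substitutions(q, 30L, spacing = 8L, first = 5L)
  h3 <- local_align(q, paste0(random_seq(200), q_mut, random_seq(200)))
  expect_lte(h3$identity_pct[1], 88)
  expect_equal(h3$matches[1], 220L)

  expect_error(local_align("ACGTACGT", subject), "at least 20")
})

make_placement_fixture <- function(seed, units_ref = 10, delta = 2, ...) {
  fx <- make_fixture(fixture_spec(motif = "CAG", units_ref = units_ref,
                                  delta_units = delta, seed = seed, ...))
  list(fx = fx, cand = fixture_candidate(fx),
       flanks = extract_flanks(fixture_candidate(fx),
                               c(ref = fx$reference_sequence)))
}

test_that("a clean expansion is PLACED with the exact enclosed segment", {
  p <- make_placement_fixture(41)
  pl <- place_flanks(p$flanks, p$fx$target_sequence)
  expect_identical(pl$status, "PLACED")
  expect_equal(nchar(pl$target_sequence), 36L)
  expect_identical(pl$target_sequence, strrep("CAG", 12))
  expect_equal(pl$identity_left, 100)
  expect_equal(pl$matches_total, 500L)
})

test_that("each rejection rule yields its typed status", {
  withr::local_seed(42)
  p <- make_placement_fixture(43)
  tr_seq <- strrep("CAG", 12)

  # right flank homology missing entirely
  one <- paste0(p$flanks$left, tr_seq, random_seq(400))
  expect_identical(place_flanks(p$flanks, one)$status, "ONE_FLANK_ONLY")

  # neither flank present
  expect_identical(place_flanks(p$flanks, random_seq(900))$status, "LOW_IDENTITY")

  # left flank embedded twice
  multi <- paste0(p$flanks$left, tr_seq, p$flanks$right, random_seq(50),
                  p$flanks$left)
  expect_identical(place_flanks(p$flanks, multi)$status, "MULTI_MAPPED")

  # flanks in the wrong order
  wrong <- paste0(p$flanks$right, tr_seq, p$flanks$left)
  expect_identical(place_flanks(p$flanks, wrong)$status, "WRONG_ORDER")

  # left flank truncated to its last 190 bp: both identities pass but
  # only 190 + 250 = 440 of 500 bases match
  trunc <- paste0(substr(p$flanks$left, 61, 250), tr_seq, p$flanks$right)
  pl <- place_flanks(p$flanks, trunc)
  expect_identical(pl$status, "COMBINED_BELOW_450")
  expect_equal(pl$matches_total, 440L)
})

test_that("a complete repeat loss places with an empty segment", {
  fx <- make_fixture(fixture_spec(motif = "CAGGT", units_ref = 6,
                                  delta_units = -6, seed = 44))
  cand <- fixture_candidate(fx)
  pl <- place_flanks(extract_flanks(cand, c(ref = fx$reference_sequence)),
                     fx$target_sequence)
  expect_identical(pl$status, "PLACED")
  expect_equal(pl$target_end - pl$target_start, 0L)
  expect_identical(pl$target_sequence, "")
})

test_that("placement is near-always exact at 2% flank SNP rate", {
  cohort <- make_cohort(
    500, list(motif = 2:6, units_ref = 5:20,
              delta_units = c(-3:-1, 1:3), flank_snp_rate = 0.02),
    seed = 909)
  placed <- 0L; exact <- 0L
  for (fx in cohort) {
    cand <- fixture_candidate(fx)
    pl <- place_flanks(extract_flanks(cand, c(ref = fx$reference_sequence)),
                       fx$target_sequence)
    if (!identical(pl$status, "PLACED")) next
    placed <- placed + 1L
    planted <- substr(fx$target_sequence, fx$tr_interval_target[1] + 1L,
                      fx$tr_interval_target[2])
    if (identical(pl$target_sequence, planted)) exact <- exact + 1L
  }
  expect_gte(placed / length(cohort), 0.95)
  expect_gte(exact / placed, 0.99)
})

test_that("growing flank divergence never moves a rejection back to PLACED", {
  withr::local_seed(55)
  for (rep in 1:5) {
    fx <- make_fixture(fixture_spec(motif = "CTTAG", units_ref = 8,
                                    delta_units = 1, seed = 600 + rep))
    cand <- fixture_candidate(fx)
    flanks <- extract_flanks(cand, c(ref = fx$reference_sequence))
    target <- fx$target_sequence
    seen_fail <- FALSE
    # cumulatively mutate the target flanks: divergence only grows
    mut_pos <- sample(setdiff(seq_len(nchar(target)),
                              seq(fx$tr_interval_target[1] + 1L,
                                  fx$tr_interval_target[2])))
    steps <- seq(0, 160, by = 20)
    applied <- 0L
    for (k in steps) {
      while (applied < k) {
        applied <- applied + 1L
        i <- mut_pos[applied]
        target <- ptrcensus:::substitute_base(target, i)
      }
      st <- place_flanks(flanks, target)$status
      if (st != "PLACED") seen_fail <- TRUE
      if (seen_fail) expect_false(st == "PLACED")
    }
    expect_true(seen_fail)  # 160 flank SNPs must defeat the 90% rule
  }
})
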