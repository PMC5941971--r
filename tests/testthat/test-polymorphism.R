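test_that("the degenerate ATT repeat is three edits from seven pure copies", {
  expect_equal(evolutionary_distance("ATTATTATCATCATTATTATC", strrep("ATT", 7)), 3L)
})

test_that("evolutionary distance basics: identity, truncation, hand example", {
  withr::local_seed(21)
  for (i in 1:20) {
    x <- random_seq(sample(1:30, 1))
    expect_equal(evolutionary_distance(x, x), 0L)
  }
  # leftmost truncation: only the first min-length bases are compared
  expect_equal(evolutionary_distance("ACGT", "ACGTTTTTTTT"), 0L)
  expect_equal(evolutionary_distance("ACGTG", "AGTGC"), 2L)
  expect_equal(enum_edit_distance("ACGTG", "AGTGC"), 2L)
  expect_error(evolutionary_distance("", "ACG"), "non-empty")
})

test_that("evolutionary distance equals independent oracles on random pairs", {
  withr::local_seed(1234)
  for (i in 1:2000) {
    a <- random_seq(sample(1:7, 1))
    b <- random_seq(sample(1:7, 1))
    expect_equal(evolutionary_distance(a, b), oracle_edit_distance(a, b))
  }
  for (i in 1:200) {  # full path enumeration on short strings
    a <- random_seq(sample(1:4, 1))
    b <- random_seq(sample(1:4, 1))
    expect_equal(evolutionary_distance(a, b), enum_edit_distance(a, b))
  }
})

test_that("test 1 accepts a near-identical prefix and rejects beyond k", {
  S <- strrep("CAG", 10)
  expect_true(test1(S, strrep("CAG", 12)))  # H = 0 <= k = 3

  withr::local_seed(61)
  S2 <- random_seq(30)
  T2 <- paste0(plant_substitutions(S2, 4L), "ACGT")
  expect_equal(oracle_edit_distance(S2, T2), 4L)  # construction check
  expect_false(test1(S2, T2))                     # 4 > k = 3

  S3 <- random_seq(9)  # k = floor(0.9) = 0: zero tolerance
  T3 <- plant_substitutions(S3, 1L)
  expect_false(test1(S3, T3))
  expect_true(test1(S3, S3))
})

test_that("test 2 checks the residual against the repeat", {
  S <- strrep("CAG", 10)
  expect_true(test2(S, strrep("CAG", 12)))  # residual CAGCAG, k' = 0

  T_bad <- paste0(S, "GGGGGG")
  expect_equal(oracle_edit_distance(S, "GGGGGG"), 4L)
  expect_false(test2(S, T_bad))

  # single-base residual equal to S's first base, k' = floor(0) = 0
  expect_true(test2(S, paste0(S, "C")))
  expect_false(test2(S, paste0(S, "T")))
  # no residual: vacuously true
  expect_true(test2(S, S))
})

test_that("thresholds follow the floor formulas", {
  th <- test_thresholds(30, 36)
  expect_equal(th$k, 3)
  expect_equal(th$k_prime, 0)  # floor(0.1 * min(30, 5))
  th2 <- test_thresholds(50, 200)
  expect_equal(th2$k, 5)
  expect_equal(th2$k_prime, 5)  # min(50, 149) -> 50
  th3 <- test_thresholds(9, 9)
  expect_equal(th3$k, 0)
  expect_equal(th3$k_prime, 0)
})

test_that("unit estimation divides total matches by motif size, rounding half away", {
  expect_equal(estimate_target_units(30, 6, 3), 12L)
  expect_equal(estimate_target_units(30, 0, 3), 10L)
  expect_equal(estimate_target_units(20, 3, 7), 3L)
  expect_equal(estimate_target_units(23, 0, 2), 12L)  # 11.5 rounds away
  expect_error(estimate_target_units(30, 6, 1), ">= 2")
})

aln <- function(matches, q, s) list(matches = matches, score = matches,
                                    query_span = q, subject_span = s)

test_that("quality classification follows the adjacency/overlap geometry", {
  # T1, T2 adjacent and S2 a prefix of S1: high
  expect_identical(classify_quality(aln(30, c(0, 30), c(0, 30)),
                                    aln(6, c(0, 6), c(30, 36)),
                                    3, 30, 6), "high")
  # small gap on T, S still overlapping, motif 5: medium
  expect_identical(classify_quality(aln(30, c(0, 30), c(0, 30)),
                                    aln(10, c(0, 10), c(32, 42)),
                                    5, 30, 12), "medium")
  # S1 and S2 disjoint: low
  expect_identical(classify_quality(aln(20, c(0, 20), c(0, 20)),
                                    aln(5, c(22, 27), c(30, 35)),
                                    5, 30, 10), "low")
  # gap beyond one motif: low
  expect_identical(classify_quality(aln(30, c(0, 30), c(0, 30)),
                                    aln(10, c(0, 10), c(40, 50)),
                                    5, 30, 20), "low")
  # small-motif rule: motif <= 4, residual < 8, matches not above half
  expect_identical(classify_quality(aln(30, c(0, 30), c(0, 30)),
                                    aln(2, c(0, 2), c(31, 33)),
                                    3, 30, 5), "low")
  expect_identical(classify_quality(aln(30, c(0, 30), c(0, 30)),
                                    aln(3, c(0, 3), c(31, 34)),
                                    3, 30, 5), "medium")
})

pure_measure <- function(motif, a, b, seed = 1) {
  fx <- make_fixture(fixture_spec(motif = motif, units_ref = a,
                                  delta_units = b - a, seed = seed))
  measure_fixture(fx)$measurement
}

test_that("pure expansions and contractions measure exactly, at high quality", {
  m <- pure_measure("CAG", 10, 12)
  expect_equal(m$delta_units, 2L)
  expect_equal(m$units_target, 12L)
  expect_identical(m$quality, "high")

  m2 <- pure_measure("CAG", 12, 10, seed = 2)
  expect_equal(m2$delta_units, -2L)
  expect_identical(m2$quality, "high")

  m3 <- pure_measure("CAG", 10, 10, seed = 3)
  expect_equal(m3$delta_units, 0L)
})

test_that("pure-repeat sweep: delta = b - a at high quality (spot grid)", {
  withr::local_seed(71)
  for (p in c(2, 3, 7, 13, 20)) {
    motif <- random_primitive_motif(p)
    for (ab in list(c(2, 3), c(2, 10), c(5, 13), c(12, 40), c(39, 40))) {
      fx <- make_fixture(fixture_spec(motif = motif, units_ref = ab[1],
                                      delta_units = ab[2] - ab[1],
                                      seed = p * 100 + ab[2]))
      m <- measure_fixture(fx)$measurement
      info <- sprintf("p=%d a=%d b=%d", p, ab[1], ab[2])
      expect_equal(m$delta_units, ab[2] - ab[1], info = info)
      expect_equal(m$units_target, ab[2], info = info)
      expect_identical(m$quality, "high", info = info)
    }
  }
})

test_that("swapping reference and target negates delta on pure repeats", {
  withr::local_seed(72)
  for (i in 1:10) {
    p <- sample(2:8, 1)
    motif <- random_primitive_motif(p)
    a <- sample(3:15, 1); b <- a + sample(1:5, 1)
    m_fwd <- pure_measure(motif, a, b, seed = 7000 + i)
    m_rev <- pure_measure(motif, b, a, seed = 8000 + i)
    expect_equal(m_fwd$delta_units, -m_rev$delta_units)
  }
})

test_that("test 1 threshold is exact: k planted substitutions pass, k+1 fail", {
  withr::local_seed(73)
  for (n in c(10, 17, 25, 33, 48, 60)) {
    k <- floor(0.1 * n)
    S <- random_seq(n)
    T_pass <- plant_substitutions(S, k)
    T_fail <- plant_substitutions(S, k + 1L)
    expect_equal(oracle_edit_distance(S, T_pass), k)
    expect_equal(oracle_edit_distance(S, T_fail), k + 1L)
    expect_true(test1(S, T_pass))
    expect_false(test1(S, T_fail))
  }
})

test_that("the best measurement ranks quality, then |delta|, deterministically", {
  ms <- data.frame(
    genome = c("g1", "g2"), delta_units = c(1L, 5L),
    units_target = c(11L, 15L), matches_aln1 = 0L, matches_aln2 = 0L,
    quality = c("high", "medium"), target_start = c(0L, 0L),
    target_end = c(10L, 10L), stringsAsFactors = FALSE)
  best <- select_best_measurement(ms)
  expect_identical(best$quality, "high")  # quality dominates |delta|
  expect_equal(best$delta_units, 1L)
  expect_equal(best$n_locations, 2L)

  ms2 <- ms; ms2$quality <- c("high", "high"); ms2$delta_units <- c(1L, -3L)
  expect_equal(select_best_measurement(ms2)$delta_units, -3L)

  expect_equal(select_best_measurement(ms[1, ])$delta_units, 1L)
  expect_error(select_best_measurement(ms[0, ]), "no measurements")
})

test_that("measure_polymorphism requires a PLACED placement", {
  fx <- make_fixture(fixture_spec(seed = 74))
  cand <- fixture_candidate(fx)
  expect_error(measure_polymorphism(cand, list(status = "ONE_FLANK_ONLY")),
               "PLACED")
})

test_that("a complete loss measures as minus the reference units, high quality", {
  fx <- make_fixture(fixture_spec(motif = "ACGGT", units_ref = 7,
                                  delta_units = -7, seed = 75))
  m <- measure_fixture(fx)$measurement
  expect_equal(m$delta_units, -7L)
  expect_equal(m$units_target, 0L)
  expect_identical(m$quality, "high")
})
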