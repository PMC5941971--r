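---
title: "Measuring tandem-repeat polymorphism between assembled genomes"
author: "ptrcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tandem-repeat polymorphism between assembled genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptrcensus)
```

## The problem

A tandem repeat (TR) is a run of adjacent, approximately identical
copies of a motif. Many TR loci are polymorphic: the number of repeat
units differs between individuals, and for dozens of loci such
expansions are disease-causing. `ptrcensus` implements a two-phase
procedure for building a catalog of *polymorphic* tandem repeats (PTR)
from assembled genomes: first a list of candidate TR on a reference is
consolidated, then each candidate is located on one or more target
assemblies and its expansion or contraction is measured by alignment.

Working from assemblies rather than short reads changes the problem:
there is no read-length ceiling on the repeats that can be measured,
but there is also no coverage-based genotyping — each target assembly
contributes a single haploid-consensus observation per locus.

## Locating a repeat on a target assembly

A repeat cannot be searched for directly: repeat sequences are not
unique, and a copy-number difference truncates any direct match.
Instead the locus is anchored by its two 250 bp *flanking regions*
(`extract_flanks()`), which are locally aligned against the image of
the host gene in the target assembly (`place_flanks()`). The choice of
250 bp balances two failure modes: shorter flanks place ambiguously,
longer ones accumulate incidental SNPs and indels until the identity
filter rejects them.

A placement is accepted only when

* each flank has exactly one qualifying hit at ≥ 90% identity
  (several near-tied qualifying hits — within 5% of the best score —
  mean the locus sits in duplicated sequence and is discarded as
  `MULTI_MAPPED`);
* the two flanks map in the correct order; and
* at least 450 of the 500 flank bases are matched. For a flank clipped
  at a sequence end the 450/500 rule scales to 90% of the available
  bases.

Every failure is a typed status, not an error, so rejection rates can
be audited. The local aligner scores +1/−1/−1 (match/mismatch/gap,
linear). Two implementation details matter for exactness:

* The enclosed segment is taken after projecting each chosen hit to
  its full flank extent. A terminal flank SNP makes the local
  alignment shave one or two columns; without the projection those
  shaved bases would leak into the enclosed segment and corrupt the
  unit estimate by ±1 at low but non-negligible rates.
* A zero-length segment (flanks adjacent in the target) is a *legal*
  placement meaning the repeat was lost entirely; it is measured as a
  contraction by the full reference unit count and graded high
  quality, since flank adjacency is direct evidence rather than an
  alignment inference.

Placement assumes the target gene image is supplied in the same
orientation as the candidate's strand; minus-strand candidates get
reverse-complemented flanks so everything proceeds 5'→3'.

## Measuring the polymorphism

Let `S` be the repeat sequence on the reference and `T` the enclosed
target segment, oriented so `S` is the shorter (`|S| = n ≤ |T| = m`).
The measurement uses the evolutionary (Sellers) distance `H` — a
unit-cost edit distance computed by a Needleman–Wunsch-style dynamic
program, with strings of unequal length aligned on their leftmost
symbol and the longer truncated (`evolutionary_distance()`). Two
checks gate the measurement:

* **Test 1** — `H(S, T[1..n]) ≤ k` with `k = ⌊0.1 n⌋`: the shorter
  repeat must be an approximate prefix of the longer.
* **Test 2** — `H(S, T[n+1..m]) ≤ k′` with
  `k′ = ⌊0.1 min(n, m−n−1)⌋`: the residual must continue the same
  motif. (The threshold uses `m−n−1` rather than the residual length
  `m−n`; see the limitations below.)

The unit count of the longer sequence is the rounded ratio of the
total matches in two local alignments — `S` vs the prefix `T[1..n]`
and `S` vs the residual `T[n+1..m]` — to the average motif size of
`S`; rounding is half-away-from-zero (the tie direction is otherwise
arbitrary and "round" alone does not fix it). Because an alignment of
`S` against the residual can contribute at most `n` matches, an
expansion beyond twice the reference length would saturate the match
count; the residual is therefore aligned against a periodic extension
(tiling) of `S`, which is exactly Test 2's premise that the residual
continues `S`'s motif. Equal-length pairs are delta 0 by definition:
substitution-only variation is not a repeat polymorphism. The two
views are computed as two independent local DPs rather than one shared
global matrix; the single-matrix formulation is a memory optimization
that yields the same match counts and spans.

**Test 3** grades each measurement from the geometry of the two
alignments (`classify_quality()`). With `S1`/`S2` the substrings of
`S` matched in the two alignments and `T1`/`T2` their counterparts on
`T` (highest score, ties to the leftmost): adjacent `T1`,`T2` with
overlapping `S1`,`S2` is **high** quality; a small gap between `T1`
and `T2` (at most one motif, configurable — one unit of drift is the
natural tolerance) with `S1`,`S2` still overlapping is **medium**;
everything else, in particular disjoint `S1`,`S2` or a failed Test 1
or 2, is **low**. For motifs of up to 4 bp whose residual alignment is
shorter than 8 bp (less than two units of change), medium additionally
requires the residual alignment to match more than half the shorter of
its two strings — with so few informative bases a spurious
residual match is otherwise too easy.

Low-quality measurements never certify a polymorphism. A locus enters
the catalog when at least one genome yields a high- or medium-quality
measurement with delta ≠ 0; across competing target locations (a
repeat hosted by several transcripts can have several images,
supplied as `"<seqid>|<tag>"` sequences) the representative
measurement is chosen by quality, then by decreasing `|delta|`, then
leftmost-first for determinism. When one genome measures delta 0 at
high quality and another measures a real polymorphism at medium
quality, the record keeps the polymorphism: ranking delta-0
measurements above it would contradict the defining rule that a locus
is polymorphic if *any* mapped transcript shows a different unit
count.

## The built-in detector

The pipeline ingests TRF `.dat` files or a generic TSV so external
detector output can be used, and also ships its own mismatch-tolerant
scanner (`detect_tandem_repeats()`) so it runs end-to-end without
external tools. The scanner seeds on the first exact motif doublet in
scan direction (smallest period wins at a position) and extends unit
by unit, charging Hamming mismatches against the seed motif. The
reported repeat is the unit prefix maximizing a +1/−2
(match/mismatch) score, with ties to the longest prefix, subject to a
global budget of ⌊0.15 × span⌋ mismatches (configurable, or an
absolute budget); extension also runs backward from the seed — a
mutated leading unit breaks the seed doublet but not the repeat —
where ties go to the shortest extension instead, because nothing
downstream of a seed forces degenerate leading units to be kept.
Scanning stops after three consecutive units that are at least half
mismatched, and such units are trimmed from the ends.

The score-with-tie-to-longest rule is what makes the detector
direction-sensitive in the documented way: on
`ATT ATT ATC ATC ATT ATT ATC` with three tolerated mismatches, a
left-to-right scan reports all seven units (the trailing `ATC` ties
the score and is kept), while a right-to-left scan seeds past the
degenerate end and reports one unit fewer. The same rule necessarily
keeps an occasional flank unit that happens to resemble the motif, so
detected boundaries are uncertain by about one unit on either side —
an inherent property of mismatch-tolerant seed extension, which is why
the detector's recovery guarantee is stated for repeats of at least 8
units, where a one-unit boundary error stays within a Jaccard overlap
of 0.9 with the true interval.

## Consolidation and finishing

Candidates from several detectors are consolidated by exact
deduplication (identical interval, motif and unit count; tool labels
are unioned — `dedupe_exact()`), then filtered
(`apply_low_quality_filters()`): loci containing ten or more
consecutive `N`, single-base motifs (homopolymer calls are detector
noise at this granularity), duplicate predictions spanning identical
nucleotides with different parameters (the parameterization whose
motif-length × unit-count best fits the span survives, ties to the
smaller motif), and spurious calls — unit count below 2, or a motif
that does not match its locus at 50% identity in any tiling frame
(the last rule is this package's operationalization; "spurious" has
no standard definition). Finally, repeats overlapping by more than
50% of the shorter member's size are removed iteratively: the shorter
of the pair goes, ties by size drop the larger motif
(`iterative_overlap_removal()`). Pairs are processed in decreasing
overlap fraction with leftmost ties first, making the fixed point
deterministic; the "50% of their size" phrase is ambiguous about
whose size, and the interpretation (shorter member) is configurable.

## Statistics utilities

Catalog comparison uses the interval Jaccard coefficient: two records
denote the same locus when intersection over union of their base
positions exceeds a threshold `j` (`match_catalogs()`,
`provenance_summary()`). "Exceeds" is strict except at `j = 1`,
where `≥` is used (strict exceedance of 1 is impossible and identity
could never match). PTR/TR ratios are stratified by motif size and
unit count with percentile-bootstrap 95% confidence intervals over
resampled loci (`ptr_tr_ratio()`, deterministic under its seed);
`delta_histogram()` tabulates signed unit differences; and
`snp_density_correlation()` tiles the analyzed regions with
non-overlapping windows (left-aligned, partial trailing windows
dropped — the tiling convention is this package's choice), then
computes Spearman's ρ between per-window mean reference unit count
and SNP count, ties by average ranks, p-value by the large-sample t
approximation. Windows with no repeat have no unit count and are
excluded; fewer than three usable windows is an error, not a number.

## The synthetic-fixture generator

`make_fixture()` plants one known polymorphism: a reference of two
i.i.d.-uniform random 400 bp flanks around `units_ref` copies of a
motif (each unit independently carrying one substitution with the
per-unit mutation rate), and a target with the same flanks mutated at
the given SNP/indel rates and the repeat expanded or contracted by
`delta_units` whole units. The target repeat inherits the reference's
(possibly mutated) units — an expansion appends pure motif copies, a
contraction truncates — mirroring how replication slippage duplicates
or deletes existing units; this also means the shared prefix of
reference and target repeat is identical, as it is between real
assemblies of related haplotypes. Options plant `N` runs and decoy
flank copies to exercise every rejection status. Everything is
deterministic under the fixture seed; cohorts derive per-fixture
seeds from one cohort seed.

What the fixtures do *not* emulate: GC structure and repeat density of
real genomes, segmental duplications at genomic scale, multi-unit
indels inside repeats, and heterozygosity. Passing the recovery suites
therefore demonstrates the correctness of the measurement machinery
under the stated noise model, not catalog-level accuracy on real
assemblies, which additionally depends on assembly quality and on the
upstream transcript mapping that this package takes as given.

## Numerical choices and problem sizes

* Rounding of unit ratios is half-away-from-zero everywhere.
* Alignment tie-breaks: best-scoring cell first by query, then
  subject position; traceback prefers diagonal, then query-gap, then
  subject-gap. This realizes the "leftmost on ties" rule and makes
  every alignment deterministic.
* Secondary hits are recovered by masking the subject span of each
  hit and re-aligning, stopping below 75% of the best score or after
  8 hits.
* The identity percentage is matches over alignment columns (the
  common aligner convention), not over query length; the alternative
  is configurable at the placement thresholds.
* Test suites run at fixed seeds with these sizes: 10,000 random
  string pairs against an independent edit-distance oracle; the
  exhaustive pure-repeat sweep (motifs 2–20 bp × all unit pairs
  2 ≤ a < b ≤ 40, 14,079 measurements); 1,000 noisy fixtures plus 500
  delta-0 nulls for recovery; 200 random interval sets against the
  overlap-removal oracle; 500 placements at 2% flank SNP rate for
  exactness. These sizes give binomial standard errors well under the
  margins asserted while keeping the default check fast.

## Known limitations

* `k′ = ⌊0.1 min(n, m−n−1)⌋` intentionally uses `m−n−1` although the
  residual has length `m−n`; the off-by-one slightly tightens the
  threshold for single-unit changes; it is the test's defining
  formula and changing it would silently shift the pass/fail boundary.
* Boundary placement of detected repeats is ±1 unit (see above);
  downstream unit estimates are anchored by the flanks, not by the
  detected boundary, so delta recovery does not inherit this error.
* The per-genome measurement treats each target sequence
  independently; no joint genotyping or allele model is attempted.
* Spurious-call screening and the near-tie multi-mapping band are
  declared heuristics with configurable thresholds, not derived
  quantities.
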