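#' Place and measure candidates against a set of target genomes
#'
#' For every candidate and every image of its host sequence in each
#' target genome, extracts the flank pair, attempts the placement and,
#' when placed, measures the polymorphism. Target genomes are named
#' lists of sequences; a sequence named `"<seqid>"` is the image of the
#' reference sequence `<seqid>`, and additional images (a gene mapped
#' to several places) can be supplied as `"<seqid>|<tag>"`.
#'
#' @param candidates Candidate data frame with `sequence` populated.
#' @param reference Named character vector of reference sequences.
#' @param targets Named list: genome label -> named character vector of
#'   target gene images.
#' @param flank_bp Flank size (default 250).
#' @param ... Passed to [place_flanks()].
#' @return Data frame with one row per attempted placement:
#'   `candidate_id`, `genome`, `image`, `status`, plus the measurement
#'   columns for `PLACED` rows.
#' @export
measure_against_genomes <- function(candidates, reference, targets,
                                    flank_bp = 250L, ...) {
  rows <- list()
  for (i in seq_len(nrow(candidates))) {
    tr <- candidates[i, ]
    flanks <- extract_flanks(tr, reference, flank_bp)
    for (g in names(targets)) {
      seqs <- targets[[g]]
      image_names <- names(seqs)[names(seqs) == tr$seqid |
                                   startsWith(names(seqs), paste0(tr$seqid, "|"))]
      for (img in image_names) {
        pl <- place_flanks(flanks, seqs[[img]], ...)
        row <- data.frame(candidate_id = i, genome = g, image = img,
                          status = pl$status, target_start = NA_integer_,
                          target_end = NA_integer_, delta_units = NA_integer_,
                          units_target = NA_integer_,
                          matches_aln1 = NA_integer_,
                          matches_aln2 = NA_integer_,
                          quality = NA_character_, stringsAsFactors = FALSE)
        if (identical(pl$status, "PLACED")) {
          m <- measure_polymorphism(tr, pl, genome = g)
          row$target_start <- m$target_start
          row$target_end <- m$target_end
          row$delta_units <- m$delta_units
          row$units_target <- m$units_target
          row$matches_aln1 <- m$matches_aln1
          row$matches_aln2 <- m$matches_aln2
          row$quality <- m$quality
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(candidate_id = integer(), genome = character(),
                      image = character(), status = character(),
                      target_start = integer(), target_end = integer(),
                      delta_units = integer(), units_target = integer(),
                      matches_aln1 = integer(), matches_aln2 = integer(),
                      quality = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Assemble catalog records from per-genome measurements
#'
#' A repeat enters the catalog when at least one target genome gives a
#' high- or medium-quality measurement with a non-zero unit difference;
#' low-quality measurements never certify a polymorphism. Each record
#' keeps all placed measurements, the set of genomes in which the locus
#' is polymorphic, and a single representative measurement chosen by
#' [select_best_measurement()] among the polymorphic measurements.
#'
#' @param candidates Candidate data frame used for the measurements.
#' @param measurements Output of [measure_against_genomes()].
#' @return A `ptr_catalog`.
#' @export
build_catalog <- function(candidates, measurements) {
  placed <- measurements[measurements$status == "PLACED", , drop = FALSE]
  records <- list()
  for (cid in unique(placed$candidate_id)) {
    ms <- placed[placed$candidate_id == cid, , drop = FALSE]
    poly_genomes <- character()
    for (g in unique(ms$genome)) {
      best_g <- select_best_measurement(ms[ms$genome == g, , drop = FALSE])
      if (best_g$quality %in% c("high", "medium") && best_g$delta_units != 0L)
        poly_genomes <- c(poly_genomes, g)
    }
    pool <- ms[ms$delta_units != 0L, , drop = FALSE]
    if (nrow(pool) == 0L) pool <- ms
    best <- select_best_measurement(pool)
    if (!(best$quality %in% c("high", "medium")) || best$delta_units == 0L)
      next
    tr <- candidates[cid, , drop = FALSE]
    rownames(tr) <- NULL
    mcols <- c("genome", "target_start", "target_end", "delta_units",
               "units_target", "matches_aln1", "matches_aln2", "quality")
    mdf <- ms[, mcols, drop = FALSE]
    rownames(mdf) <- NULL
    records[[length(records) + 1L]] <-
      list(tr = tr, measurements = mdf,
           best = best[c(mcols, "n_locations")],
           polymorphic_genomes = sort(poly_genomes))
  }
  new_catalog(records)
}

#' Remove heavily overlapping catalog records
#'
#' Applies the iterative >50% overlap rule of
#' [iterative_overlap_removal()] to the reference intervals of the
#' catalog records.
#'
#' @param catalog A `ptr_catalog`.
#' @param ... Passed to [iterative_overlap_removal()].
#' @return The pruned `ptr_catalog`.
#' @export
finish_catalog <- function(catalog, ...) {
  if (length(catalog$records) <= 1L) return(catalog)
  trs <- do.call(rbind, lapply(catalog$records, function(r) r$tr))
  trs$.rec <- seq_along(catalog$records)
  kept <- iterative_overlap_removal(trs, ...)
  new_catalog(catalog$records[sort(kept$.rec)])
}

#' Trace catalog records back to discovery tools and target genomes
#'
#' Counts how many records are attributable to exactly one versus
#' several discovery tools, and to one versus several target genomes.
#' When the raw per-tool candidate lists are supplied, a record is
#' attributed to a tool if any of that tool's candidates matches the
#' record's reference interval at Jaccard coefficient above `j`
#' (`>= j` for `j = 1`, where strict exceedance is impossible);
#' otherwise the `tools` annotation carried by the record is used.
#'
#' @param catalog A `ptr_catalog`.
#' @param j Jaccard threshold in `(0, 1]` (default 0.7).
#' @param tool_candidates Optional candidate data frame with a `tools`
#'   column holding a single tool label per row.
#' @return List: `per_tool_ptr_counts`, `per_genome_ptr_counts`,
#'   `single_tool`, `multi_tool`, `single_genome`, `multi_genome`, `j`.
#' @export
provenance_summary <- function(catalog, j = 0.7, tool_candidates = NULL) {
  stopifnot(j > 0, j <= 1)
  recs <- catalog$records
  tool_sets <- lapply(recs, function(r) {
    if (is.null(tool_candidates))
      return(unique(strsplit(r$tr$tools, ",", fixed = TRUE)[[1]]))
    jc <- jaccard_vec(r$tr$seqid, r$tr$start, r$tr$end, tool_candidates)
    hit <- if (j == 1) jc >= j else jc > j
    unique(unlist(strsplit(tool_candidates$tools[hit], ",", fixed = TRUE)))
  })
  genome_sets <- lapply(recs, function(r) r$polymorphic_genomes)
  count_by <- function(sets) {
    tab <- table(unlist(sets))
    stats::setNames(as.integer(tab), names(tab))
  }
  list(per_tool_ptr_counts = count_by(tool_sets),
       per_genome_ptr_counts = count_by(genome_sets),
       single_tool = sum(lengths(tool_sets) == 1L),
       multi_tool = sum(lengths(tool_sets) > 1L),
       single_genome = sum(lengths(genome_sets) == 1L),
       multi_genome = sum(lengths(genome_sets) > 1L),
       j = j)
}

#' Run the full census pipeline on in-memory genomes
#'
#' Detects candidates on the reference (unless supplied), consolidates
#' and filters them, measures polymorphism against each target genome,
#' assembles the catalog and prunes overlapping records.
#'
#' @param reference Named character vector of reference sequences.
#' @param targets Named list of target genomes (see
#'   [measure_against_genomes()]).
#' @param candidates Optional pre-computed candidate data frame; when
#'   `NULL` the built-in detector scans every reference sequence.
#' @param transcripts Optional transcript data frame; when given, only
#'   merged transcript regions (extended by `region_pad_bp`) are
#'   scanned.
#' @param region_pad_bp Extension of merged regions before detection
#'   (default 1000).
#' @param flank_bp Flank size for placement (default 250).
#' @param ... Passed to [detect_tandem_repeats()].
#' @return List: `catalog` (finished `ptr_catalog`), `candidates`
#'   (after filtering), `rejected`, `measurements`, `per_tool_counts`.
#' @export
run_ptr_census <- function(reference, targets, candidates = NULL,
                           transcripts = NULL, region_pad_bp = 1000L,
                           flank_bp = 250L, ...) {
  if (is.null(candidates)) {
    scan <- if (!is.null(transcripts)) {
      regions <- prepare_regions(transcripts, reference, region_pad_bp)
      stats::setNames(
        lapply(seq_len(nrow(regions)), function(i)
          list(seq = regions$sequence[i], seqid = regions$seqid[i],
               offset = regions$start[i], strand = regions$strand[i])),
        paste0("region", seq_len(nrow(regions))))
    } else {
      stats::setNames(
        lapply(names(reference), function(s)
          list(seq = reference[[s]], seqid = s, offset = 0L, strand = "+")),
        names(reference))
    }
    candidates <- do.call(rbind, lapply(scan, function(r)
      detections_to_candidates(detect_tandem_repeats(r$seq, ...),
                               r$seqid, r$strand, r$offset,
                               region_length = nchar(r$seq))))
    if (is.null(candidates)) candidates <- empty_candidates()
    rownames(candidates) <- NULL
  }
  pool <- dedupe_exact(candidates)
  cands <- populate_sequences(pool$candidates, reference)
  filt <- apply_low_quality_filters(cands)
  kept <- filt$kept
  rownames(kept) <- NULL
  measurements <- measure_against_genomes(kept, reference, targets,
                                          flank_bp = flank_bp)
  catalog <- finish_catalog(build_catalog(kept, measurements))
  list(catalog = catalog, candidates = kept, rejected = filt$rejected,
       measurements = measurements, per_tool_counts = pool$per_tool_counts)
}
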