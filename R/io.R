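#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased; `N` and other IUPAC ambiguity codes are
#' preserved verbatim. Record order follows the file.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one entry per record; names are the
#'   first whitespace-delimited word of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop("malformed FASTA: line ", nonblank[1], " is not a header")
  hdr <- which(startsWith(lines, ">"))
  after <- c(hdr[-1] - 1L, length(lines))
  for (i in seq_along(hdr)) {
    body <- lines[seq.int(hdr[i] + 1L, length.out = max(0L, after[i] - hdr[i]))]
    if (!any(nzchar(trimws(body))))
      stop("malformed FASTA: empty record at line ", hdr[i])
  }
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

empty_candidates <- function() {
  data.frame(seqid = character(), start = integer(), end = integer(),
             strand = character(), motif = character(), units = numeric(),
             sequence = character(), tools = character(),
             stringsAsFactors = FALSE)
}

#' Parse a Tandem Repeats Finder `.dat` file
#'
#' Understands the standard TRF table dialect: optional `Sequence:`
#' headers followed by whitespace-separated records
#' (start end period copy-number consensus-size %match %indel score
#' A C G T entropy motif sequence). TRF coordinates are 1-based
#' inclusive and are converted to the package's 0-based half-open
#' convention.
#'
#' @param path Path to a `.dat` file.
#' @param default_seqid Sequence id used for records that appear before
#'   any `Sequence:` header.
#' @return Candidate data frame (`seqid`, `start`, `end`, `strand`,
#'   `motif`, `units`, `sequence`, `tools`), `tools = "TRF"`.
#' @export
parse_trf_dat <- function(path, default_seqid = "seq") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  seqid <- default_seqid
  rows <- list()
  rec <- 0L
  for (ln in lines) {
    t <- trimws(ln)
    if (!nzchar(t)) next
    if (startsWith(t, "Sequence:")) {
      seqid <- sub("\\s.*$", "", trimws(sub("^Sequence:", "", t)))
      next
    }
    if (!grepl("^[0-9]", t)) next  # parameter banner lines etc.
    f <- strsplit(t, "\\s+")[[1]]
    rec <- rec + 1L
    if (length(f) < 15L)
      stop("TRF record ", rec, ": expected 15 fields, got ", length(f))
    num <- suppressWarnings(as.numeric(f[1:13]))
    if (any(is.na(num)))
      stop("TRF record ", rec, ": non-numeric field")
    rows[[rec]] <- data.frame(
      seqid = seqid, start = as.integer(num[1]) - 1L,
      end = as.integer(num[2]), strand = "+",
      motif = toupper(f[14]), units = num[4],
      sequence = toupper(f[15]), tools = "TRF",
      stringsAsFactors = FALSE)
  }
  if (rec == 0L) return(empty_candidates())
  do.call(rbind, rows)
}

#' Read/write the generic TR candidate TSV
#'
#' A plain tab-separated exchange format (`seqid`, `start`, `end`,
#' `strand`, `motif`, `units`, `sequence`, `tools`; 0-based half-open)
#' so that output of external detectors can be converted and ingested.
#'
#' @param path File path.
#' @return `read_tr_tsv()` returns a candidate data frame.
#' @export
read_tr_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  need <- c("seqid", "start", "end", "strand", "motif", "units")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("TR TSV missing columns: ", paste(miss, collapse = ", "))
  out <- data.frame(
    seqid = df$seqid, start = as.integer(df$start), end = as.integer(df$end),
    strand = df$strand, motif = toupper(df$motif), units = as.numeric(df$units),
    sequence = if ("sequence" %in% names(df)) toupper(df$sequence) else NA_character_,
    tools = if ("tools" %in% names(df)) df$tools else "unknown",
    stringsAsFactors = FALSE)
  out
}

#' @rdname read_tr_tsv
#' @param candidates Candidate data frame.
#' @export
write_tr_tsv <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Fill the locus sequence of candidates from a genome
#'
#' @param candidates Candidate data frame.
#' @param genome Named character vector of sequences.
#' @return The candidates with `sequence` populated.
#' @export
populate_sequences <- function(candidates, genome) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates$sequence <- vapply(seq_len(nrow(candidates)), function(i) {
    extract_sequence(genome, candidates[i, ])
  }, character(1))
  candidates
}

catalog_tsv_columns <- c(
  "record_id", "seqid", "start", "end", "strand", "motif", "units_ref",
  "tools", "genome", "target_start", "target_end", "delta_units",
  "units_target", "matches_aln1", "matches_aln2", "quality", "is_best",
  "polymorphic_genomes")

#' Write a PTR catalog as a tab-separated file
#'
#' One row per (record, measurement); the representative measurement of
#' each record carries `is_best = 1`. Reference and target coordinates
#' are emitted 1-based inclusive in the TSV (use [write_catalog_bed()]
#' for a 0-based half-open BED view). `read_catalog()` inverts the
#' conversion, so write-then-read is the identity.
#'
#' @param catalog A `ptr_catalog` (see [build_catalog()]).
#' @param path Output path.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "ptr_catalog"))
  rows <- list()
  for (i in seq_along(catalog$records)) {
    r <- catalog$records[[i]]
    ms <- r$measurements
    best_key <- paste(r$best$genome, r$best$target_start, r$best$target_end,
                      r$best$delta_units, r$best$quality)
    keys <- paste(ms$genome, ms$target_start, ms$target_end,
                  ms$delta_units, ms$quality)
    is_best <- as.integer(seq_len(nrow(ms)) == match(best_key, keys))
    rows[[i]] <- data.frame(
      record_id = i, seqid = r$tr$seqid,
      start = r$tr$start + 1L, end = r$tr$end, strand = r$tr$strand,
      motif = r$tr$motif, units_ref = r$tr$units, tools = r$tr$tools,
      genome = ms$genome,
      target_start = ms$target_start + 1L, target_end = ms$target_end,
      delta_units = ms$delta_units, units_target = ms$units_target,
      matches_aln1 = ms$matches_aln1, matches_aln2 = ms$matches_aln2,
      quality = ms$quality, is_best = is_best,
      polymorphic_genomes = paste(r$polymorphic_genomes, collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(catalog_tsv_columns))),
                    catalog_tsv_columns)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(catalog_tsv_columns, collapse = "\t"), con)
  if (nrow(out))
    utils::write.table(out[, catalog_tsv_columns], con, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @return `read_catalog()` returns a `ptr_catalog`.
#' @export
read_catalog <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (nrow(df) == 0L) return(new_catalog(list()))
  for (col in c("record_id", "start", "end", "target_start", "target_end",
                "delta_units", "units_target", "matches_aln1",
                "matches_aln2", "is_best"))
    df[[col]] <- as.integer(df[[col]])
  df$units_ref <- as.numeric(df$units_ref)
  records <- lapply(split(df, df$record_id)[order(unique(df$record_id))],
                    function(g) {
    tr <- data.frame(seqid = g$seqid[1], start = g$start[1] - 1L,
                     end = g$end[1], strand = g$strand[1], motif = g$motif[1],
                     units = g$units_ref[1],
                     sequence = NA_character_, tools = g$tools[1],
                     stringsAsFactors = FALSE)
    ms <- data.frame(genome = g$genome,
                     target_start = g$target_start - 1L,
                     target_end = g$target_end,
                     delta_units = g$delta_units,
                     units_target = g$units_target,
                     matches_aln1 = g$matches_aln1,
                     matches_aln2 = g$matches_aln2,
                     quality = g$quality, stringsAsFactors = FALSE)
    pg <- g$polymorphic_genomes[1]
    list(tr = tr, measurements = ms,
         best = as.list(ms[which(g$is_best == 1L)[1], ]),
         polymorphic_genomes = if (nzchar(pg))
           strsplit(pg, ",", fixed = TRUE)[[1]] else character())
  })
  new_catalog(unname(records))
}

new_catalog <- function(records) {
  structure(list(records = records), class = "ptr_catalog")
}

#' @export
print.ptr_catalog <- function(x, ...) {
  cat("PTR catalog with", length(x$records), "records\n")
  invisible(x)
}

#' @export
length.ptr_catalog <- function(x) length(x$records)

#' Flatten a catalog to one row per record (its best measurement)
#'
#' @param x A `ptr_catalog`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @method as.data.frame ptr_catalog
#' @export
as.data.frame.ptr_catalog <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (length(x$records) == 0L)
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), motif = character(),
                      units = numeric(), tools = character(),
                      delta_units = integer(), units_target = integer(),
                      quality = character(), genome = character(),
                      n_locations = integer(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(x$records, function(r) {
    data.frame(seqid = r$tr$seqid, start = r$tr$start, end = r$tr$end,
               strand = r$tr$strand, motif = r$tr$motif, units = r$tr$units,
               tools = r$tr$tools, delta_units = r$best$delta_units,
               units_target = r$best$units_target, quality = r$best$quality,
               genome = r$best$genome, n_locations = nrow(r$measurements),
               stringsAsFactors = FALSE)
  }))
}

#' Export catalog loci as BED (0-based half-open)
#'
#' @param catalog A `ptr_catalog`.
#' @param path Output path.
#' @export
write_catalog_bed <- function(catalog, path) {
  df <- as.data.frame(catalog)
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  gr <- as_granges0(df)
  names(gr) <- sprintf("%s_x%s_d%+d", df$motif, format(df$units), df$delta_units)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED path.
#' @return Interval data frame (0-based half-open) with a `name` column
#'   when present in the file.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_df0(gr)
  df$strand[df$strand == "*"] <- "+"
  if (!is.null(gr$name)) df$name <- gr$name
  df
}

#' Write intervals as BED
#'
#' @param df Interval data frame (optionally with `name`).
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  gr <- as_granges0(df)
  if (!is.null(df$name)) names(gr) <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
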