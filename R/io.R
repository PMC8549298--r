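#' Read long reads from FASTA or FASTQ
#'
#' Parses a (optionally gzipped) FASTA or FASTQ file into a read table.
#' Lowercase bases are uppercased and any non-ACGT character becomes `N`;
#' FASTQ base qualities are retained as phred+33 strings.
#'
#' @param path Input file; gzip is detected transparently.
#' @param format `"fasta"`, `"fastq"`, or `"auto"` (sniff the first record).
#' @return A tibble with columns `id`, `sequence`, `quality` (phred+33 string
#'   or `NA`), `length`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") format <- sniff_format(path)

  if (format == "fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) abort(sprintf("failed to parse '%s' as FASTA: %s",
                                        path, conditionMessage(e)))
    )
    qual <- rep(NA_character_, length(set))
  } else {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
      error = function(e) abort(sprintf("failed to parse '%s' as FASTQ: %s",
                                        path, conditionMessage(e)))
    )
    q <- S4Vectors::mcols(set)$qualities
    qual <- if (is.null(q)) rep(NA_character_, length(set)) else as.character(q)
  }

  ids <- unname(sub("\\s.*$", "", names(set) %||% character(0)))
  seqs <- unname(sanitize_dna(as.character(set)))
  qual <- unname(qual)
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1]
    abort(sprintf("duplicate read id '%s' (record %d) in %s", ids[dup], dup, path))
  }
  bad <- which(nzchar(qual) & !is.na(qual) & nchar(qual) != nchar(seqs))
  if (length(bad) > 0) {
    abort(sprintf("record %d ('%s'): quality length differs from sequence length",
                  bad[1], ids[bad[1]]))
  }
  tibble(id = ids, sequence = seqs, quality = qual, length = nchar(seqs))
}

sanitize_dna <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

sniff_format <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  first <- readLines(con, n = 1L)
  if (length(first) == 0) return("fasta")
  if (startsWith(first, ">")) "fasta"
  else if (startsWith(first, "@")) "fastq"
  else abort(sprintf("cannot determine format of %s: first byte is neither '>' nor '@'", path))
}

#' Decode phred+33 quality strings to integer scores
#'
#' @param x Character vector of phred+33 quality strings.
#' @return A list of integer vectors (NA elements stay `NULL`).
#' @export
phred_scores <- function(x) {
  lapply(x, function(q) {
    if (is.na(q)) return(NULL)
    as.integer(utf8ToInt(q)) - 33L
  })
}

#' Write reads or contigs as FASTA
#'
#' @param x A tibble with `id` and `sequence` columns (reads, super reads or
#'   contigs), or a named character vector.
#' @param path Output path (`.gz` compresses).
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 80L) {
  if (is.character(x)) {
    x <- tibble(id = names(x), sequence = unname(x))
  }
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

paf_cols <- c("query_id", "query_len", "query_start", "query_end", "strand",
              "target_id", "target_len", "target_start", "target_end",
              "n_matches", "block_len", "mapq")

empty_overlaps <- function() {
  tibble(query_id = character(), query_len = integer(),
         query_start = integer(), query_end = integer(),
         strand = character(),
         target_id = character(), target_len = integer(),
         target_start = integer(), target_end = integer(),
         n_matches = integer(), block_len = integer(), mapq = integer(),
         identity = numeric())
}

#' Read pairwise overlaps from PAF
#'
#' Parses the 12 mandatory PAF columns (coordinates 0-based, half-open, on the
#' forward strand of each read) and derives `identity = n_matches/block_len`.
#'
#' @param path PAF file (optionally gzipped).
#' @return An overlap tibble.
#' @export
read_paf <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_overlaps())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12)) {
    abort(sprintf("PAF line %d: expected >= 12 tab-separated columns, got %d",
                  which(nf < 12)[1], nf[which(nf < 12)[1]]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  ints <- function(i) {
    v <- suppressWarnings(as.integer(get(i)))
    if (anyNA(v)) abort(sprintf("PAF line %d: column %d is not an integer",
                                which(is.na(v))[1], i))
    v
  }
  ov <- tibble(
    query_id = get(1), query_len = ints(2),
    query_start = ints(3), query_end = ints(4),
    strand = get(5),
    target_id = get(6), target_len = ints(7),
    target_start = ints(8), target_end = ints(9),
    n_matches = ints(10), block_len = ints(11), mapq = ints(12)
  )
  if (!all(ov$strand %in% c("+", "-"))) {
    abort(sprintf("PAF line %d: strand must be '+' or '-'",
                  which(!ov$strand %in% c("+", "-"))[1]))
  }
  bad <- which(!(ov$query_start >= 0 & ov$query_start < ov$query_end &
                 ov$query_end <= ov$query_len &
                 ov$target_start >= 0 & ov$target_start < ov$target_end &
                 ov$target_end <= ov$target_len))
  if (length(bad) > 0) {
    abort(sprintf("PAF line %d: coordinates out of range [0, length]", bad[1]))
  }
  if (any(ov$n_matches > ov$block_len)) {
    abort(sprintf("PAF line %d: n_matches exceeds block_len",
                  which(ov$n_matches > ov$block_len)[1]))
  }
  ov$identity <- ov$n_matches / ov$block_len
  ov
}

#' Write overlaps as PAF
#'
#' Writes the 12 mandatory PAF fields; `write_paf()` then `read_paf()` is the
#' identity on them.
#'
#' @param overlaps Overlap tibble (as from [compute_overlaps()] or [read_paf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(overlaps, path) {
  m <- overlaps[, paf_cols]
  lines <- do.call(paste, c(unname(as.list(m)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
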