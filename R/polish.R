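#' Map reads to a reference sequence
#'
#' Read-vs-reference mode of the minimizer seed-chain-align machinery: each
#' read is anchored on both strands, the strand with the longer colinear
#' anchor chain wins, and a chain-guided banded fitting alignment (read
#' end-to-end, reference free at both ends) produces a base-level alignment.
#' The result stores, per read, the aligned reference span, the strand, the
#' edit distance, a "row" string giving the read base aligned to every
#' reference position (`-` for deletions), a parallel quality string, and
#' insertion records.
#'
#' @param reference Reference sequence (character scalar).
#' @param reads Read tibble (`id`, `sequence`, optional `quality`).
#' @param params [assembly_params()].
#' @param min_anchors Minimum chained anchors for a mapping.
#' @param pad Reference window padding in bases.
#' @return An object of class `hb_alignments`: list with `tbl` (per-read
#'   mapping table), `rows`, `qrows`, `ins`, `ref_len`.
#' @export
map_reads <- function(reference, reads, params = assembly_params(),
                      min_anchors = 3L, pad = 100L) {
  qual <- if ("quality" %in% names(reads)) reads$quality else rep(NA_character_, nrow(reads))
  res <- cpp_map_reads(reference, reads$sequence, qual,
                       k = params$k, w = params$w,
                       min_shared = as.integer(min_anchors), max_occ = 200L,
                       band_frac = params$band_frac, min_hw = 48L,
                       pad = as.integer(pad))
  # reads without base qualities vote with uniform weight in the pileup
  res$qrow[is.na(qual)] <- NA_character_
  ins <- as_tibble(res$ins)
  ins$read_id <- reads$id[ins$read]
  structure(list(
    tbl = tibble(read_id = reads$id, ok = res$ok, strand = res$strand,
                 ref_start = res$ref_start, ref_end = res$ref_end,
                 q_start = res$q_start, q_end = res$q_end, dist = res$dist,
                 has_qual = !is.na(qual)),
    rows = res$row, qrows = res$qrow, ins = ins,
    ref_len = nchar(reference)
  ), class = "hb_alignments")
}

#' @export
print.hb_alignments <- function(x, ...) {
  cat(sprintf("<hb_alignments> %d/%d reads mapped to a %d bp reference\n",
              sum(x$tbl$ok), nrow(x$tbl), x$ref_len))
  invisible(x)
}

#' Pileup polishing of an assembled sequence
#'
#' Per round: all reads are mapped to the sequence, a full pileup is built
#' from the base-level alignments, and every column is replaced by its
#' (quality-)weighted majority symbol — including deletion; insertions are
#' applied when a majority of the reads covering a junction carry the same
#' inserted string. Plays the role a windowed consensus polisher fills in
#' large-scale pipelines; clusters here are small enough for a single full
#' pileup.
#'
#' @param sequence Sequence to polish.
#' @param reads Read tibble.
#' @param params [assembly_params()].
#' @param rounds Number of polishing rounds (default `params$polish_rounds`).
#' @return The polished sequence, with per-base read depth in attribute
#'   `coverage` and the final-round alignments in attribute `alignments`.
#' @export
polish <- function(sequence, reads, params = assembly_params(),
                   rounds = params$polish_rounds) {
  cov <- rep(0L, nchar(sequence))
  aln <- NULL
  for (r in seq_len(max(rounds, 0L))) {
    aln <- map_reads(sequence, reads, params)
    keep <- which(aln$tbl$ok)
    if (length(keep) == 0) {
      warn("polish: no read maps to the sequence; returning it unchanged")
      return(structure(sequence, coverage = cov, alignments = aln))
    }
    ins <- aln$ins[aln$ins$read %in% keep, , drop = FALSE]
    cons <- cpp_consensus(sequence, aln$tbl$ref_start[keep], aln$rows[keep],
                          aln$qrows[keep], ins$read, ins$pos, ins$seq)
    sequence <- cons$seq
    cov <- cons$cov
  }
  structure(sequence, coverage = cov, alignments = aln)
}
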