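#' Compute all-vs-all read overlaps
#'
#' Internal minimizer-based overlapper: reads are sketched with (k, w)
#' minimizers (k = 15; w = 10 for HiFi, 5 for CLR/ONT), candidate pairs must
#' share at least three minimizers, seed anchors are chained colinearly
#' (longest increasing subsequence), and identity is estimated by a banded
#' edit-distance alignment whose band follows the anchor chain. Overlaps whose
#' chain overhang is small are extended to the read ends, so proper dovetails
#' carry end-to-end coordinates. One overlap per orientation is reported per
#' unordered pair, with the lexicographically smaller read id as query.
#'
#' The result is unfiltered: pass it through [classify_and_filter()] before
#' graph construction.
#'
#' @param reads Read tibble (from [read_sequences()] or the simulator).
#' @param params [assembly_params()].
#' @param min_shared Minimum shared minimizers for a candidate pair.
#' @param max_occ Ignore minimizers occurring more than this many times
#'   (repeat filter).
#' @return An overlap tibble in PAF column layout plus `identity`.
#' @export
compute_overlaps <- function(reads, params = assembly_params(),
                             min_shared = 3L, max_occ = 200L) {
  stopifnot(nrow(reads) >= 1)
  reads <- dplyr::arrange(reads, .data$id)
  res <- cpp_find_overlaps(reads$sequence,
                           k = params$k, w = params$w,
                           min_shared = as.integer(min_shared),
                           max_occ = as.integer(max_occ),
                           band_frac = params$band_frac, min_hw = 48L,
                           min_span = as.integer(min(500L, params$min_ovlp_len)),
                           max_hang_ext = params$max_hang)
  if (nrow(res) == 0) return(empty_overlaps())
  lens <- nchar(reads$sequence)
  tibble(
    query_id = reads$id[res$qi], query_len = lens[res$qi],
    query_start = res$qs, query_end = res$qe,
    strand = res$strand,
    target_id = reads$id[res$ti], target_len = lens[res$ti],
    target_start = res$ts, target_end = res$te,
    n_matches = res$nmatch, block_len = res$blocklen,
    mapq = 255L,
    identity = res$nmatch / pmax(1L, res$blocklen)
  )
}

#' Classify overlaps and keep proper dovetails
#'
#' Classifies each overlap as dovetail, containment, internal match or
#' self-overlap and retains the usable ones. With the query coordinates
#' flipped for `-` strand overlaps, the overhang is
#' `min(qstart', tstart) + min(qlen - qend', tlen - tend)`; an overlap is an
#' internal (repeat-induced) match when the overhang exceeds
#' `min(max_hang, int_frac * block_len)`. Processing order: self-overlaps,
#' exact duplicates, classification, then length/identity thresholds.
#'
#' @param overlaps Overlap tibble (internal overlapper or imported PAF).
#' @param params [assembly_params()]; supplies `min_ovlp_len`, `min_identity`,
#'   `max_hang`, `int_frac`.
#' @param keep_containments Keep containment overlaps in the output (needed
#'   for clustering, where reads contained in the seed are cluster members).
#'   Contained reads are excluded from graph building either way.
#' @return The retained overlaps with an `olclass` column.
#' @export
classify_and_filter <- function(overlaps, params = assembly_params(),
                                keep_containments = FALSE) {
  if (nrow(overlaps) == 0) {
    out <- empty_overlaps()
    out$olclass <- character()
    return(out)
  }
  ov <- dplyr::filter(overlaps, .data$query_id != .data$target_id)
  ov <- dplyr::distinct(ov, dplyr::across(dplyr::all_of(paf_cols)),
                        .keep_all = TRUE)
  ov$olclass <- classify_overlaps(ov, params$max_hang, params$int_frac)
  keep_classes <- c("dovetail_qsuffix_tprefix", "dovetail_qprefix_tsuffix")
  if (keep_containments) {
    keep_classes <- c(keep_classes, "query_contained", "target_contained")
  }
  dplyr::filter(ov,
                .data$olclass %in% keep_classes,
                .data$block_len >= params$min_ovlp_len,
                .data$identity >= params$min_identity)
}

classify_overlaps <- function(ov, max_hang = 1000L, int_frac = 0.8) {
  neg <- ov$strand == "-"
  qs <- ifelse(neg, ov$query_len - ov$query_end, ov$query_start)
  qe <- ifelse(neg, ov$query_len - ov$query_start, ov$query_end)
  lq <- ov$query_len - qe
  rt <- ov$target_len - ov$target_end
  overhang <- pmin(qs, ov$target_start) + pmin(lq, rt)
  maxoh <- pmin(max_hang, int_frac * ov$block_len)
  dplyr::case_when(
    ov$query_id == ov$target_id ~ "self",
    overhang > maxoh ~ "internal",
    qs <= ov$target_start & lq <= rt ~ "query_contained",
    qs >= ov$target_start & lq >= rt ~ "target_contained",
    qs > ov$target_start ~ "dovetail_qsuffix_tprefix",
    TRUE ~ "dovetail_qprefix_tsuffix"
  )
}
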