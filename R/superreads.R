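#' Error-correct the reads of one phase group
#'
#' MSA-pileup self-correction within a haplotype-specific read group: the
#' group's reads are assembled into a group-local backbone (overlap graph,
#' longest path), all group reads are aligned to it, and the pileup-majority
#' symbol over each read's aligned span is projected back onto the read.
#' Unaligned read ends are left untouched. Because the group's reads stem
#' from one haplotype, true variation is not erased by the consensus.
#'
#' @param group_reads Read tibble of one phase group.
#' @param params [assembly_params()].
#' @return The read tibble with corrected `sequence` (qualities dropped).
#' @export
correct_group_reads <- function(group_reads, params = assembly_params()) {
  if (nrow(group_reads) <= 1) return(group_reads)
  ov <- classify_and_filter(compute_overlaps(group_reads, params), params,
                            keep_containments = TRUE)
  backbone <- assemble_longest_path(group_reads, ov, params)$sequence
  # polish the backbone first: a consensus against the raw (high-error)
  # backbone would leave correlated residual errors in every corrected read
  backbone <- as.character(polish(backbone, group_reads, params))
  aln <- map_reads(backbone, group_reads, params)
  keep <- which(aln$tbl$ok)
  if (length(keep) < 2) return(group_reads)

  corrected <- group_reads$sequence
  for (i in keep) {
    t <- aln$tbl[i, ]
    cs <- t$ref_start + 1L
    ce <- t$ref_end
    if (ce < cs) next
    mid <- substr(backbone, cs, ce)
    s <- group_reads$sequence[i]
    if (t$strand == "-") s <- rc_dna(s)
    new <- paste0(substr(s, 1L, t$q_start), mid,
                  substr(s, t$q_end + 1L, nchar(s)))
    if (t$strand == "-") new <- rc_dna(new)
    corrected[i] <- new
  }
  out <- group_reads
  out$sequence <- corrected
  out$length <- nchar(corrected)
  if ("quality" %in% names(out)) out$quality <- NA_character_
  out
}

#' Assemble one phase group into a super read
#'
#' The group's (corrected) reads are assembled through a fresh overlap graph
#' (transitive reduction, longest path, overlap-aware concatenation) and the
#' result is polished against the group reads; the coverage profile of the
#' polishing alignments is recorded for trimming.
#'
#' @param group_reads Read tibble of one phase group (corrected when
#'   correction is on).
#' @param params [assembly_params()].
#' @param cluster_id,phase Identifiers stored on the super read; `phase` is
#'   1, 2, or 0 for unphased.
#' @param polish_reads Reads used as polishing evidence (defaults to
#'   `group_reads`). When group correction is on, the pipeline passes the
#'   group's *raw* reads here: corrected reads are consensus projections
#'   whose errors are correlated, so only the raw reads carry independent
#'   evidence for a consensus vote.
#' @return A one-row super-read tibble: `id`, `cluster_id`, `phase`,
#'   `sequence`, `length`, `coverage` (list column), `constituent_ids`
#'   (list column), `n_reads`.
#' @export
build_super_read <- function(group_reads, params = assembly_params(),
                             cluster_id = 0L, phase = 0L,
                             polish_reads = group_reads) {
  stopifnot(nrow(group_reads) >= 1)
  if (nrow(group_reads) == 1) {
    seqv <- group_reads$sequence[1]
    return(tibble(
      id = sprintf("sr_c%d_p%d", cluster_id, phase),
      cluster_id = as.integer(cluster_id), phase = as.integer(phase),
      sequence = seqv, length = nchar(seqv),
      coverage = list(rep(1L, nchar(seqv))),
      constituent_ids = list(group_reads$id),
      n_reads = 1L
    ))
  }
  ov <- classify_and_filter(compute_overlaps(group_reads, params), params,
                            keep_containments = TRUE)
  backbone <- assemble_longest_path(group_reads, ov, params)$sequence
  pol <- polish(backbone, polish_reads, params)
  tibble(
    id = sprintf("sr_c%d_p%d", cluster_id, phase),
    cluster_id = as.integer(cluster_id), phase = as.integer(phase),
    sequence = as.character(pol), length = nchar(pol),
    coverage = list(as.integer(attr(pol, "coverage"))),
    constituent_ids = list(group_reads$id),
    n_reads = nrow(group_reads)
  )
}

#' Trim low-coverage super-read ends
#'
#' Keeps the longest contiguous interval with read coverage of at least 2 and
#' discards the super read when that interval is shorter than
#' `params$min_ovlp_len`. Single-read overhangs at super-read ends carry most
#' of the residual errors, which this removes.
#'
#' @param sr Super-read tibble (one or more rows).
#' @param params [assembly_params()].
#' @param min_cov Coverage threshold (default 2).
#' @return The trimmed super-read tibble (possibly with fewer rows).
#' @export
trim_super_read <- function(sr, params = assembly_params(), min_cov = 2L) {
  if (nrow(sr) == 0) return(sr)
  keep <- logical(nrow(sr))
  for (i in seq_len(nrow(sr))) {
    cov <- sr$coverage[[i]]
    iv <- longest_run(cov >= min_cov)
    if (is.null(iv) || (iv[2] - iv[1] + 1L) < params$min_ovlp_len) next
    keep[i] <- TRUE
    sr$sequence[i] <- substr(sr$sequence[i], iv[1], iv[2])
    sr$length[i] <- iv[2] - iv[1] + 1L
    sr$coverage[[i]] <- cov[iv[1]:iv[2]]
  }
  sr[keep, , drop = FALSE]
}

# longest TRUE run; returns c(start, end) 1-based or NULL
longest_run <- function(x) {
  if (!any(x)) return(NULL)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values)
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], ends[best])
}
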