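#' N50 family of contiguity statistics
#'
#' `n50_value(lengths)` is the largest length L such that pieces of length L
#' or longer sum to at least half of `total` (the assembly size by default;
#' pass a genome size for NG50/NGA50). `NA` when half of `total` is never
#' reached.
#'
#' @param lengths Piece lengths (contigs or alignment blocks).
#' @param total Reference total (defaults to `sum(lengths)`).
#' @return A length or `NA`.
#' @export
n50_value <- function(lengths, total = sum(lengths)) {
  lengths <- lengths[lengths > 0]
  if (length(lengths) == 0 || total <= 0) return(NA_integer_)
  s <- sort(lengths, decreasing = TRUE)
  i <- which(cumsum(s) >= total / 2)[1]
  if (is.na(i)) NA_integer_ else as.integer(s[i])
}

#' Evaluate an assembly against a simulated diploid truth
#'
#' Every contig is aligned to both truth haplotypes with the internal
#' seed-chain aligner and assigned to the haplotype it matches best. Metrics:
#'
#' * haplotype coverage: covered truth bases over both haplotypes / total
#'   truth bases, in percent;
#' * switch error rate: among adjacent heterozygous-site pairs covered by a
#'   contig, the percentage whose contig alleles switch haplotype;
#' * N50 of contig lengths; NG50 against the diploid genome size
#'   (both haplotypes); NGA50 from alignment blocks split at misassembly
#'   breakpoints (haplotype switches, or alignment discontinuities over 1 kb);
#' * duplication ratio: aligned contig bases / covered truth bases;
#' * QV: phred-scaled contig base error rate against the best haplotype
#'   (capped at 60 when no error is observed).
#'
#' @param contigs Contig tibble (`id`, `sequence`) — or any sequence tibble.
#' @param truth [simulate_diploid()] object.
#' @param params [assembly_params()] controlling the aligner.
#' @return A one-row tibble of class `hb_eval`; per-contig details are in
#'   attribute `contig_detail` (also via `tidy()`).
#' @export
evaluate_assembly <- function(contigs, truth, params = assembly_params()) {
  haps <- c(truth$hap1, truth$hap2)
  glen <- nchar(truth$hap1) + nchar(truth$hap2)
  if (nrow(contigs) == 0) {
    out <- tibble(haplotype_coverage = 0, switch_error_rate = NA_real_,
                  n50 = NA_integer_, ng50 = NA_integer_, nga50 = NA_integer_,
                  duplication_ratio = NA_real_, qv_identity = NA_real_,
                  n_contigs = 0L, total_len = 0L)
    return(structure(out, class = c("hb_eval", class(out)),
                     contig_detail = tibble()))
  }
  ctbl <- tibble(id = contigs$id, sequence = contigs$sequence,
                 quality = NA_character_, length = nchar(contigs$sequence))

  aln1 <- map_reads(truth$hap1, ctbl, params, pad = 200L)
  aln2 <- map_reads(truth$hap2, ctbl, params, pad = 200L)

  het <- truth$het_sites
  detail <- vector("list", nrow(ctbl))
  cov_iv <- list(`1` = NULL, `2` = NULL)
  tot_aln <- 0
  tot_err <- 0
  sw_pairs <- 0L
  sw_switch <- 0L
  blocks <- numeric(0)

  for (i in seq_len(nrow(ctbl))) {
    a1 <- aln1$tbl[i, ]; a2 <- aln2$tbl[i, ]
    id1 <- if (isTRUE(a1$ok)) 1 - a1$dist / max(1, a1$ref_end - a1$ref_start) else NA
    id2 <- if (isTRUE(a2$ok)) 1 - a2$dist / max(1, a2$ref_end - a2$ref_start) else NA
    if (is.na(id1) && is.na(id2)) {
      detail[[i]] <- tibble(id = ctbl$id[i], best_hap = NA_integer_,
                            identity = NA_real_, aligned_len = 0L,
                            n_sites = 0L, n_switches = 0L)
      next
    }
    best <- if (is.na(id2) || (!is.na(id1) && id1 >= id2)) 1L else 2L
    ab <- if (best == 1L) a1 else a2
    alen <- ab$ref_end - ab$ref_start
    tot_aln <- tot_aln + alen
    tot_err <- tot_err + ab$dist
    key <- as.character(best)
    cov_iv[[key]] <- rbind(cov_iv[[key]], c(ab$ref_start, ab$ref_end))

    # haplotype label per covered het site, read off the hap1 alignment
    n_sites <- 0L
    n_sw <- 0L
    if (isTRUE(a1$ok) && nrow(het) > 0) {
      inside <- which(het$position >= a1$ref_start & het$position < a1$ref_end)
      if (length(inside) > 0) {
        off <- het$position[inside] - a1$ref_start + 1L
        base <- substr(rep(aln1$rows[i], length(off)), off, off)
        lab <- ifelse(base == het$hap1_allele[inside], 1L,
                      ifelse(base == het$hap2_allele[inside], 2L, NA_integer_))
        pos <- het$position[inside][!is.na(lab)]
        lab <- lab[!is.na(lab)]
        n_sites <- length(lab)
        if (n_sites >= 2) {
          sw <- lab[-1] != lab[-n_sites]
          n_sw <- sum(sw)
          sw_pairs <- sw_pairs + n_sites - 1L
          sw_switch <- sw_switch + n_sw
          # NGA50 blocks: split at switch midpoints, extend to alignment ends
          bnd <- c(a1$ref_start,
                   floor((pos[-1][sw] + pos[-n_sites][sw]) / 2),
                   a1$ref_end)
          blocks <- c(blocks, diff(bnd))
        } else {
          sw_pairs <- sw_pairs + max(0L, n_sites - 1L)
          blocks <- c(blocks, alen)
        }
      } else {
        blocks <- c(blocks, alen)
      }
    } else {
      blocks <- c(blocks, alen)
    }
    detail[[i]] <- tibble(id = ctbl$id[i], best_hap = best,
                          identity = if (best == 1L) id1 else id2,
                          aligned_len = as.integer(alen),
                          n_sites = n_sites, n_switches = n_sw)
  }
  detail <- dplyr::bind_rows(detail)

  covered <- vapply(1:2, function(h) {
    iv <- cov_iv[[as.character(h)]]
    if (is.null(iv)) return(0)
    union_len(iv)
  }, numeric(1))
  hc <- 100 * sum(covered) / glen
  dup <- if (sum(covered) > 0) tot_aln / sum(covered) else NA_real_
  err_rate <- if (tot_aln > 0) tot_err / tot_aln else NA_real_
  qv <- if (is.na(err_rate)) NA_real_
        else if (err_rate <= 0) 60 else min(60, -10 * log10(err_rate))
  sw_rate <- if (sw_pairs > 0) 100 * sw_switch / sw_pairs else NA_real_

  out <- tibble(
    haplotype_coverage = hc,
    switch_error_rate = sw_rate,
    n50 = n50_value(ctbl$length),
    ng50 = n50_value(ctbl$length, total = glen),
    nga50 = n50_value(blocks, total = glen),
    duplication_ratio = dup,
    qv_identity = qv,
    n_contigs = nrow(ctbl),
    total_len = sum(ctbl$length)
  )
  structure(out, class = c("hb_eval", class(out)), contig_detail = detail)
}

union_len <- function(iv) {
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  tot <- 0
  cur_s <- iv[1, 1]; cur_e <- iv[1, 2]
  if (nrow(iv) > 1) {
    for (r in 2:nrow(iv)) {
      if (iv[r, 1] > cur_e) {
        tot <- tot + cur_e - cur_s
        cur_s <- iv[r, 1]; cur_e <- iv[r, 2]
      } else {
        cur_e <- max(cur_e, iv[r, 2])
      }
    }
  }
  tot + cur_e - cur_s
}

#' @export
tidy.hb_eval <- function(x, ...) attr(x, "contig_detail")

#' @export
glance.hb_eval <- function(x, ...) as_tibble(x)

#' @export
print.hb_eval <- function(x, ...) {
  cat("<hb_eval>\n")
  cat(sprintf("  haplotype coverage: %.1f%%   switch error: %s\n",
              x$haplotype_coverage,
              ifelse(is.na(x$switch_error_rate), "NA",
                     sprintf("%.2f%%", x$switch_error_rate))))
  cat(sprintf("  N50 %s  NG50 %s  NGA50 %s  dup %.2f  QV %.1f  (%d contigs, %d bp)\n",
              format(x$n50), format(x$ng50), format(x$nga50),
              x$duplication_ratio, x$qv_identity, x$n_contigs, x$total_len))
  invisible(x)
}
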