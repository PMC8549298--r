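#' Call candidate heterozygous SNPs from a read pileup
#'
#' Pileup-based heterozygous site discovery on the (polished) ad hoc
#' reference: a site is emitted iff its base depth is at least `min_depth`,
#' both the reference and the strongest alternative allele are seen at least
#' `min_count` times, and the alternative allele fraction lies within
#' `af_range`. Substitutions only; indels are not used as phasing markers.
#'
#' @param aln [map_reads()] result of the cluster reads against the reference.
#' @param reference The reference the reads were mapped to.
#' @param params [assembly_params()] (unused thresholds kept explicit below).
#' @param min_depth Minimum base depth (default 10).
#' @param min_count Minimum count of each allele (default 3).
#' @param af_range Allowed alternative allele fraction (default `c(0.2, 0.8)`).
#' @return A tibble of sites: `position` (0-based), `ref_allele`,
#'   `alt_allele`, `depth`, `ref_count`, `alt_count`, `af`.
#' @export
call_snps <- function(aln, reference, params = assembly_params(),
                      min_depth = 10L, min_count = 3L, af_range = c(0.2, 0.8)) {
  empty <- tibble(position = integer(), ref_allele = character(),
                  alt_allele = character(), depth = integer(),
                  ref_count = integer(), alt_count = integer(), af = numeric())
  keep <- which(aln$tbl$ok)
  if (length(keep) == 0 || nchar(reference) == 0) return(empty)
  counts <- cpp_base_counts(nchar(reference), aln$tbl$ref_start[keep],
                            aln$rows[keep])
  bases <- c("A", "C", "G", "T")
  m <- t(counts[1:4, , drop = FALSE])            # L x 4
  refv <- strsplit(reference, "")[[1]]
  ridx <- match(refv, bases)
  depth <- rowSums(m)
  ok_pos <- which(!is.na(ridx) & depth >= min_depth)
  if (length(ok_pos) == 0) return(empty)
  ref_count <- m[cbind(ok_pos, ridx[ok_pos])]
  malt <- m[ok_pos, , drop = FALSE]
  malt[cbind(seq_along(ok_pos), ridx[ok_pos])] <- -1L
  alt_idx <- max.col(malt, ties.method = "first")
  alt_count <- m[cbind(ok_pos, alt_idx)]
  af <- alt_count / pmax(1L, ref_count + alt_count)
  sel <- ref_count >= min_count & alt_count >= min_count &
    af >= af_range[1] & af <= af_range[2]
  tibble(position = ok_pos[sel] - 1L,
         ref_allele = refv[ok_pos[sel]],
         alt_allele = bases[alt_idx[sel]],
         depth = as.integer(depth[ok_pos[sel]]),
         ref_count = as.integer(ref_count[sel]),
         alt_count = as.integer(alt_count[sel]),
         af = af[sel])
}

#' Build the allele matrix (the wMEC instance)
#'
#' One row per read, one column per called site. An entry is 0 when the
#' read's aligned base equals the reference allele, 1 when it equals the
#' alternative allele, and missing when the site is uncovered, deleted, or
#' carries a third allele. Entry weights are phred base qualities where
#' available, otherwise a constant 10.
#'
#' @param aln [map_reads()] result.
#' @param sites Site tibble from [call_snps()].
#' @param default_weight Weight for entries without base qualities.
#' @return An object of class `allele_matrix`: list with integer matrix `m`
#'   (reads x sites, `NA` = missing), weight matrix `w`, and `sites`.
#' @export
build_allele_matrix <- function(aln, sites, default_weight = 10) {
  ids <- aln$tbl$read_id
  n <- length(ids)
  s <- nrow(sites)
  m <- matrix(NA_integer_, n, s, dimnames = list(ids, NULL))
  w <- matrix(NA_real_, n, s, dimnames = list(ids, NULL))
  if (s == 0 || n == 0) {
    return(structure(list(m = m, w = w, sites = sites), class = "allele_matrix"))
  }
  starts <- aln$tbl$ref_start
  ends <- aln$tbl$ref_end
  okv <- aln$tbl$ok
  for (j in seq_len(s)) {
    p <- sites$position[j]
    idx <- which(okv & starts <= p & ends > p)
    if (length(idx) == 0) next
    off <- p - starts[idx] + 1L
    base <- substr(aln$rows[idx], off, off)
    allele <- ifelse(base == sites$ref_allele[j], 0L,
                     ifelse(base == sites$alt_allele[j], 1L, NA_integer_))
    qc <- substr(aln$qrows[idx], off, off)
    hq <- aln$tbl$has_qual[idx] & !is.na(qc) & nzchar(qc)
    wt <- rep(default_weight, length(idx))
    if (any(hq)) {
      wt[hq] <- pmax(1, vapply(qc[hq], function(ch) utf8ToInt(ch) - 33,
                               numeric(1), USE.NAMES = FALSE))
    }
    m[idx, j] <- allele
    w[idx, j] <- ifelse(is.na(allele), NA_real_, wt)
  }
  structure(list(m = m, w = w, sites = sites), class = "allele_matrix")
}

#' @export
print.allele_matrix <- function(x, ...) {
  cat(sprintf("<allele_matrix> %d reads x %d sites, %d entries\n",
              nrow(x$m), ncol(x$m), sum(!is.na(x$m))))
  invisible(x)
}

#' Solve weighted minimum error correction
#'
#' Exact column-sweep dynamic programming over bipartitions of each column's
#' active reads: per column the cost of a bipartition is, for each side, the
#' minimum over the two allele assignments of the summed weights of
#' disagreeing entries; transitions must agree on reads shared between
#' consecutive columns; the backtrace yields the global minimum-cost
#' bipartition of the rows. Columns whose active coverage exceeds
#' `params$max_phasing_coverage` are downsampled first: the longest-spanning
#' reads are kept, and dropped reads are truncated from the offending column
#' onwards (ties broken by a ranking seeded with `params$rng_seed`). Reads
#' removed from the dynamic program are assigned afterwards to the side whose
#' inferred alleles they disagree with least.
#'
#' Output labels are canonical: H1 is the group containing the
#' lexicographically smallest assigned read id.
#'
#' @param am [build_allele_matrix()] result.
#' @param params [assembly_params()].
#' @return An object of class `hb_phasing`: list with `assignment` (tibble
#'   `read_id`, `haplotype` in `{"H1","H2"}` for every read with at least one
#'   matrix entry), `mec_cost`, `n_sites`.
#' @export
solve_wmec <- function(am, params = assembly_params()) {
  m <- am$m
  w <- am$w
  has_entry <- rowSums(!is.na(m)) > 0
  if (ncol(m) == 0 || !any(has_entry)) {
    return(structure(list(
      assignment = tibble(read_id = character(), haplotype = character()),
      mec_cost = 0, n_sites = ncol(m)
    ), class = "hb_phasing"))
  }
  m2 <- m[has_entry, , drop = FALSE]
  w2 <- w[has_entry, , drop = FALSE]
  ds <- downsample_matrix(m2, w2, params$max_phasing_coverage, params$rng_seed)

  ent <- which(!is.na(ds$m), arr.ind = TRUE)
  dp_rows <- sort(unique(ent[, 1]))
  row_map <- match(ent[, 1], dp_rows)
  res <- cpp_wmec(row = row_map - 1L, col = ent[, 2] - 1L,
                  allele = ds$m[ent], weight = ds$w[ent],
                  n_rows = length(dp_rows), n_cols = ncol(ds$m))

  side <- setNames(rep(NA_integer_, nrow(m2)), rownames(m2))
  side[dp_rows] <- res$side

  # side-allele consensus per column, for post-hoc assignment of rows the
  # downsampler removed from the DP
  if (any(is.na(side))) {
    consensus <- matrix(NA_integer_, 2, ncol(m2))
    for (s in 0:1) {
      rows_s <- which(side == s)
      if (length(rows_s) == 0) next
      for (j in seq_len(ncol(m2))) {
        e <- ds$m[rows_s, j]
        ww <- ds$w[rows_s, j]
        if (all(is.na(e))) next
        w1 <- sum(ww[which(e == 1L)], na.rm = TRUE)
        w0 <- sum(ww[which(e == 0L)], na.rm = TRUE)
        consensus[s + 1, j] <- as.integer(w1 > w0)
      }
    }
    for (r in which(is.na(side))) {
      e <- m2[r, ]
      ww <- w2[r, ]
      cost_s <- vapply(1:2, function(s) {
        dis <- !is.na(e) & !is.na(consensus[s, ]) & e != consensus[s, ]
        sum(ww[dis])
      }, numeric(1))
      side[r] <- if (cost_s[2] < cost_s[1]) 1L else 0L
    }
  }

  lab <- ifelse(side == 0L, "H1", "H2")
  smallest <- sort(names(side))[1]
  if (lab[[smallest]] == "H2") lab <- ifelse(lab == "H1", "H2", "H1")
  structure(list(
    assignment = tibble(read_id = names(side), haplotype = unname(lab)),
    mec_cost = res$cost,
    n_sites = ncol(m)
  ), class = "hb_phasing")
}

# per-column coverage capping: sweep columns left to right; when the number of
# reads spanning a column exceeds `cap`, truncate the shortest-spanning reads
# from this column onwards (span = covered site interval; ties by seeded rank)
downsample_matrix <- function(m, w, cap, seed) {
  n <- nrow(m)
  s <- ncol(m)
  first <- apply(m, 1, function(x) {
    nn <- which(!is.na(x))
    if (length(nn) == 0) NA_integer_ else nn[1]
  })
  last <- apply(m, 1, function(x) {
    nn <- which(!is.na(x))
    if (length(nn) == 0) NA_integer_ else nn[length(nn)]
  })
  tiebreak <- withr::with_seed(seed, sample.int(n))
  for (j in seq_len(s)) {
    act <- which(!is.na(first) & first <= j & last >= j)
    if (length(act) <= cap) next
    span <- last[act] - pmax(first[act], j) + 1L
    keep_ord <- order(-span, tiebreak[act])
    drop <- act[keep_ord[(cap + 1):length(act)]]
    for (r in drop) {
      m[r, j:s] <- NA_integer_
      w[r, j:s] <- NA_real_
      nn <- which(!is.na(m[r, ]))
      if (length(nn) == 0) {
        first[r] <- NA_integer_
        last[r] <- NA_integer_
      } else {
        last[r] <- nn[length(nn)]
      }
    }
  }
  list(m = m, w = w)
}

#' @export
print.hb_phasing <- function(x, ...) {
  tab <- table(x$assignment$haplotype)
  cat(sprintf("<hb_phasing> %d reads phased over %d sites (MEC cost %.1f): %s\n",
              nrow(x$assignment), x$n_sites, x$mec_cost,
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
tidy.hb_phasing <- function(x, ...) x$assignment

#' @export
glance.hb_phasing <- function(x, ...) {
  tibble(n_reads = nrow(x$assignment), n_sites = x$n_sites,
         mec_cost = x$mec_cost,
         n_h1 = sum(x$assignment$haplotype == "H1"),
         n_h2 = sum(x$assignment$haplotype == "H2"))
}

#' Complete a phasing over all cluster reads
#'
#' Reads absent from the allele matrix or covering no called site cannot be
#' phased; they are assigned to both haplotypes so that they contribute to
#' both super reads. When no site was called at all (a homozygous cluster),
#' every read is assigned to both groups and a single unphased super read
#' results.
#'
#' @param cluster_read_ids Ids of all reads in the cluster.
#' @param phasing [solve_wmec()] result.
#' @return A tibble `read_id`, `label` with labels in `{"H1","H2","both"}`.
#' @export
assign_unphased <- function(cluster_read_ids, phasing) {
  lab <- setNames(rep("both", length(cluster_read_ids)), cluster_read_ids)
  if (phasing$n_sites > 0 && nrow(phasing$assignment) > 0) {
    hit <- phasing$assignment$read_id %in% cluster_read_ids
    lab[phasing$assignment$read_id[hit]] <- phasing$assignment$haplotype[hit]
  }
  tibble(read_id = names(lab), label = unname(lab))
}
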