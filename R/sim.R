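#' Simulate a diploid genome with ground truth
#'
#' Haplotype 1 is uniform random DNA; haplotype 2 is derived from it by
#' Bernoulli(`snp_rate`) substitutions (uniform over the three alternative
#' bases) and Bernoulli(`indel_rate`) indel events of 1-10 bp (insertion or
#' deletion with equal probability). Heterozygous SNP positions and alleles
#' are recorded in haplotype-1 coordinates; applying the substitutions and
#' then the indels to haplotype 1 yields haplotype 2. Fully deterministic
#' given `seed`.
#'
#' @param hap_len Haplotype length in bases.
#' @param snp_rate Per-base substitution heterozygosity (default 0.01).
#' @param indel_rate Per-base indel event rate (default 0).
#' @param seed Integer seed.
#' @return An object of class `diploid_truth`: list with `hap1`, `hap2`,
#'   `het_sites` (tibble `position` 0-based on hap1, `hap1_allele`,
#'   `hap2_allele`), `indels` (tibble `position`, `type`, `seq`), `seed`.
#' @export
simulate_diploid <- function(hap_len, snp_rate = 0.01, indel_rate = 0,
                             seed = 1L) {
  stopifnot(hap_len > 0, snp_rate >= 0, snp_rate <= 0.1,
            indel_rate >= 0, indel_rate <= 0.1)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    h1 <- sample(bases, hap_len, replace = TRUE)
    sub_pos <- which(runif(hap_len) < snp_rate)
    h2 <- h1
    if (length(sub_pos) > 0) {
      alt <- vapply(h1[sub_pos],
                    function(b) sample(setdiff(bases, b), 1L),
                    character(1), USE.NAMES = FALSE)
      h2[sub_pos] <- alt
    }
    het <- tibble(position = sub_pos - 1L,
                  hap1_allele = h1[sub_pos],
                  hap2_allele = h2[sub_pos])
    ind_pos <- which(runif(hap_len) < indel_rate)
    indels <- tibble(position = integer(), type = character(),
                     seq = character())
    if (length(ind_pos) > 0) {
      typ <- sample(c("ins", "del"), length(ind_pos), replace = TRUE)
      len <- sample(1:10, length(ind_pos), replace = TRUE)
      insseq <- vapply(len, function(l) paste(sample(bases, l, replace = TRUE),
                                              collapse = ""), character(1))
      indels <- tibble(position = ind_pos - 1L, type = typ,
                       seq = ifelse(typ == "ins", insseq, NA_character_),
                       len = len)
      # apply right-to-left so earlier positions stay valid
      h2s <- h2
      for (i in rev(seq_len(nrow(indels)))) {
        p <- indels$position[i] + 1L
        if (indels$type[i] == "ins") {
          h2s <- append(h2s, strsplit(indels$seq[i], "")[[1]], after = p)
        } else {
          del_to <- min(length(h2s), p + indels$len[i] - 1L)
          h2s <- h2s[-(p:del_to)]
        }
      }
      h2 <- h2s
      # het sites falling inside deleted regions no longer separate haplotypes
      if (any(typ == "del")) {
        delet <- indels[indels$type == "del", ]
        bad <- rep(FALSE, nrow(het))
        for (i in seq_len(nrow(delet))) {
          bad <- bad | (het$position >= delet$position[i] &
                        het$position < delet$position[i] + delet$len[i])
        }
        het <- het[!bad, , drop = FALSE]
      }
    }
    structure(list(hap1 = paste(h1, collapse = ""),
                   hap2 = paste(h2, collapse = ""),
                   het_sites = het, indels = indels, seed = seed),
              class = "diploid_truth")
  })
}

#' @export
print.diploid_truth <- function(x, ...) {
  cat(sprintf("<diploid_truth> hap1 %d bp, hap2 %d bp, %d het SNPs, %d indels\n",
              nchar(x$hap1), nchar(x$hap2), nrow(x$het_sites), nrow(x$indels)))
  invisible(x)
}

#' Simulate platform-style long reads from a diploid truth
#'
#' Read lengths are lognormal with the requested mean and standard deviation
#' (clamped to at least 500 bp and at most the haplotype length); start
#' positions are uniform; reads are drawn from each haplotype (random strand)
#' until the per-haplotype coverage target is met. Sequencing errors are
#' i.i.d. per base: substitutions to a uniform different base, single-base
#' insertions after a base, and deletions, at the stated rates. Ground-truth
#' haplotype of origin, coordinates and strand are recorded per read.
#'
#' @param truth A [simulate_diploid()] object.
#' @param coverage_per_hap Target coverage per haplotype (default 20).
#' @param mean_len,len_sd Read length distribution in bases (defaults 10000
#'   and 2000).
#' @param err_sub,err_ins,err_del Per-base error rates (defaults 0).
#' @param seed Integer seed.
#' @return A list with `reads` (read tibble; `quality` is `NA`) and
#'   `read_truth` (tibble `id`, `hap`, `start`, `end`, `strand`; coordinates
#'   0-based half-open on the source haplotype).
#' @export
simulate_reads <- function(truth, coverage_per_hap = 20, mean_len = 10000,
                           len_sd = 2000, err_sub = 0, err_ins = 0,
                           err_del = 0, seed = 1L) {
  stopifnot(coverage_per_hap > 0, err_sub >= 0, err_ins >= 0, err_del >= 0)
  bases <- c("A", "C", "G", "T")
  sdlog <- sqrt(log(1 + (len_sd / mean_len)^2))
  meanlog <- log(mean_len) - sdlog^2 / 2

  withr::with_seed(seed, {
    all_reads <- list()
    all_truth <- list()
    ctr <- 0L
    for (hap in 1:2) {
      hseq <- if (hap == 1) truth$hap1 else truth$hap2
      hlen <- nchar(hseq)
      got <- 0
      target <- coverage_per_hap * hlen
      while (got < target) {
        len <- round(rlnorm(1, meanlog, sdlog))
        len <- max(500L, min(as.integer(len), hlen))
        start <- sample.int(hlen - len + 1L, 1L) - 1L
        frag <- substr(hseq, start + 1L, start + len)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") frag <- rc_dna(frag)
        if (err_sub > 0 || err_ins > 0 || err_del > 0) {
          frag <- apply_errors(frag, err_sub, err_ins, err_del, bases)
        }
        ctr <- ctr + 1L
        id <- sprintf("r%05d_h%d", ctr, hap)
        all_reads[[ctr]] <- tibble(id = id, sequence = frag,
                                   quality = NA_character_,
                                   length = nchar(frag))
        all_truth[[ctr]] <- tibble(id = id, hap = hap, start = start,
                                   end = start + len, strand = strand)
        got <- got + len
      }
    }
    list(reads = dplyr::bind_rows(all_reads),
         read_truth = dplyr::bind_rows(all_truth))
  })
}

apply_errors <- function(seq, err_sub, err_ins, err_del, bases) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sub_i <- which(runif(n) < err_sub)
  if (length(sub_i) > 0) {
    shift <- sample.int(3L, length(sub_i), replace = TRUE)
    cur <- match(ch[sub_i], bases)
    cur[is.na(cur)] <- 1L
    ch[sub_i] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  del_i <- runif(n) < err_del
  ins_i <- which(runif(n) < err_ins)
  pieces <- ch
  pieces[del_i] <- ""
  if (length(ins_i) > 0) {
    ins_b <- sample(bases, length(ins_i), replace = TRUE)
    pieces[ins_i] <- paste0(pieces[ins_i], ins_b)
  }
  paste(pieces, collapse = "")
}
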