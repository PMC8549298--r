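#' Plot contig lengths of an assembly
#'
#' Contig lengths in decreasing order, the standard at-a-glance contiguity
#' view.
#'
#' @param object An `hb_assembly`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hb_assembly <- function(object, ...) {
  d <- object$contigs %>%
    dplyr::arrange(dplyr::desc(.data$length)) %>%
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$length)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "contig rank", y = "length (bp)",
                  title = "Contig lengths") +
    ggplot2::theme_minimal()
}

#' Plot per-contig evaluation detail
#'
#' Aligned length per contig, coloured by assigned haplotype, with switch
#' counts in the label.
#'
#' @param object An `hb_eval` result.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.hb_eval <- function(object, ...) {
  d <- attr(object, "contig_detail")
  if (is.null(d) || nrow(d) == 0) {
    abort("no contig detail to plot (empty assembly?)")
  }
  d$hap <- factor(d$best_hap, levels = c(1, 2), labels = c("hap1", "hap2"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$id, y = .data$aligned_len,
                                  fill = .data$hap)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "aligned bases", fill = "haplotype",
                  title = "Contig-to-haplotype alignment") +
    ggplot2::theme_minimal()
}

#' Plot the allele matrix of a cluster
#'
#' Reads by site heatmap of 0/1 alleles, the visual form of a wMEC instance.
#'
#' @param object An `allele_matrix`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.allele_matrix <- function(object, ...) {
  m <- object$m
  if (ncol(m) == 0) abort("allele matrix has no sites")
  d <- tibble(
    read = rep(rownames(m), times = ncol(m)),
    site = rep(seq_len(ncol(m)), each = nrow(m)),
    allele = as.vector(m)
  )
  d <- d[!is.na(d$allele), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$site, y = .data$read,
                                  fill = factor(.data$allele))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`0` = "#4477AA", `1` = "#EE6677")) +
    ggplot2::labs(x = "het site", y = NULL, fill = "allele",
                  title = "Allele matrix (wMEC instance)") +
    ggplot2::theme_minimal()
}
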