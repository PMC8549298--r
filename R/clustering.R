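#' Partition reads into seed-centred clusters
#'
#' The divide stage: reads are sorted by length in descending order; in each
#' iteration the longest unprocessed read is picked as the seed and its
#' cluster is the seed plus every unprocessed read with a retained overlap to
#' it. All cluster members are then discarded from the sorted list, and the
#' loop continues until every read is processed. Length ties break
#' lexicographically by read id, so the result is deterministic.
#'
#' Clusters partition the read set; clusters of size one are carried forward
#' (their read can still become an unphased super read).
#'
#' @param reads Read tibble.
#' @param overlaps Retained overlaps from [classify_and_filter()]. Pass
#'   `keep_containments = TRUE` output so that reads contained in the seed
#'   join its cluster.
#' @return A tibble with columns `cluster_id`, `seed_id`, `member_id` (one
#'   row per member; the seed is a member of its own cluster).
#' @export
build_clusters <- function(reads, overlaps) {
  ord <- order(-reads$length, reads$id)
  ids <- reads$id[ord]

  nbr <- new.env(parent = emptyenv())
  if (nrow(overlaps) > 0) {
    add <- function(a, b) {
      for (i in seq_along(a)) {
        key <- a[[i]]
        nbr[[key]] <- c(nbr[[key]], b[[i]])
      }
    }
    add(overlaps$query_id, overlaps$target_id)
    add(overlaps$target_id, overlaps$query_id)
  }

  processed <- new.env(parent = emptyenv())
  out <- vector("list", length(ids))
  cl <- 0L
  for (seed in ids) {
    if (!is.null(processed[[seed]])) next
    cl <- cl + 1L
    cand <- unique(nbr[[seed]] %||% character(0))
    members <- c(seed, cand[vapply(cand, function(x) is.null(processed[[x]]),
                                   logical(1))])
    for (m in members) processed[[m]] <- TRUE
    out[[cl]] <- tibble(cluster_id = cl, seed_id = seed, member_id = members)
  }
  dplyr::bind_rows(out[seq_len(cl)])
}
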