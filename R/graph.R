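#' Build a directed read overlap graph
#'
#' Nodes are the non-contained input sequences; a directed edge `v -> w`
#' records a retained dovetail overlap in which the suffix of `v` matches the
#' prefix of `w`. Reverse-strand overlaps are resolved by assigning every
#' read an orientation through a breadth-first sweep over the overlap
#' adjacency; overlaps inconsistent with the assigned orientations (odd
#' cycles) are dropped, later input rows first. Each edge carries the
#' extension weight (bases `w` adds beyond `v`) and the cut position of `w`'s
#' oriented sequence where the appended suffix starts.
#'
#' @param reads Tibble of member sequences (`id`, `sequence`, `length`).
#' @param overlaps Classified overlaps ([classify_and_filter()] output;
#'   containment rows, when present, mark reads to exclude from the graph).
#' @param params [assembly_params()].
#' @param contain_identity Minimum containment identity for a read to be
#'   absorbed (dropped from the graph). Defaults to `params$min_identity`;
#'   the super-read graph uses a stricter bar so that a haplotype block is
#'   never swallowed by its near-identical cross-haplotype counterpart.
#' @return An igraph with vertex attributes `len`, `orient` and edge
#'   attributes `ext`, `cut`, `ovlen`, `identity`.
#' @export
build_overlap_graph <- function(reads, overlaps, params = assembly_params(),
                                contain_identity = params$min_identity) {
  contained <- character(0)
  if (nrow(overlaps) > 0 && "olclass" %in% names(overlaps)) {
    qc <- overlaps$olclass == "query_contained" &
      overlaps$identity >= contain_identity
    tc <- overlaps$olclass == "target_contained" &
      overlaps$identity >= contain_identity
    contained <- unique(c(overlaps$query_id[qc], overlaps$target_id[tc]))
  }
  nodes <- reads[!reads$id %in% contained, , drop = FALSE]
  if (nrow(nodes) == 0) nodes <- reads[which.max(reads$length), , drop = FALSE]
  dov <- overlaps[overlaps$olclass %in% c("dovetail_qsuffix_tprefix",
                                          "dovetail_qprefix_tsuffix") &
                  overlaps$query_id %in% nodes$id &
                  overlaps$target_id %in% nodes$id, , drop = FALSE]

  orient <- assign_orientations(nodes, dov)

  vertices <- data.frame(name = nodes$id, len = nodes$length,
                         orient = orient[nodes$id],
                         stringsAsFactors = FALSE)
  if (nrow(dov) == 0) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = character(0), to = character(0), ext = integer(0),
                 cut = integer(0), ovlen = integer(0), identity = numeric(0)),
      directed = TRUE, vertices = vertices)
    g <- igraph::set_graph_attr(g, "absorbed", contained)
    return(g)
  }

  oq <- orient[dov$query_id]
  ot <- orient[dov$target_id]
  neg <- dov$strand == "-"
  consistent <- xor(oq == 1L, ot == 1L) == neg
  dov <- dov[consistent, , drop = FALSE]
  oq <- oq[consistent]; ot <- ot[consistent]

  qs <- ifelse(oq == 1L, dov$query_len - dov$query_end, dov$query_start)
  qe <- ifelse(oq == 1L, dov$query_len - dov$query_start, dov$query_end)
  ts <- ifelse(ot == 1L, dov$target_len - dov$target_end, dov$target_start)
  te <- ifelse(ot == 1L, dov$target_len - dov$target_start, dov$target_end)

  q_first <- qs > ts | (qs == ts & (dov$query_len - qe) <= (dov$target_len - te))
  from <- ifelse(q_first, dov$query_id, dov$target_id)
  to <- ifelse(q_first, dov$target_id, dov$query_id)
  ext <- ifelse(q_first, dov$target_len - te, dov$query_len - qe)
  cut <- ifelse(q_first, te, qe)

  edges <- tibble(from = from, to = to, ext = as.integer(ext),
                  cut = as.integer(cut), ovlen = dov$block_len,
                  identity = dov$identity)
  edges <- edges[edges$ext > 0 & edges$from != edges$to, , drop = FALSE]
  # one edge per ordered pair: keep the longest overlap
  edges <- edges %>%
    dplyr::arrange(dplyr::desc(.data$ovlen)) %>%
    dplyr::distinct(.data$from, .data$to, .keep_all = TRUE)

  g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                     vertices = vertices)
  igraph::set_graph_attr(g, "absorbed", contained)
}

# breadth-first orientation assignment over the dovetail adjacency;
# '-' strand overlaps join reads of opposite orientation
assign_orientations <- function(nodes, dov) {
  orient <- setNames(rep(NA_integer_, nrow(nodes)), nodes$id)
  if (nrow(dov) > 0) {
    adj <- list()
    for (i in seq_len(nrow(dov))) {
      q <- dov$query_id[i]; t <- dov$target_id[i]
      flip <- as.integer(dov$strand[i] == "-")
      adj[[q]] <- rbind(adj[[q]], c(t, flip))
      adj[[t]] <- rbind(adj[[t]], c(q, flip))
    }
  } else {
    adj <- list()
  }
  start_order <- nodes$id[order(-nodes$length, nodes$id)]
  for (s in start_order) {
    if (!is.na(orient[s])) next
    orient[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 1]
        if (!u %in% names(orient) || !is.na(orient[u])) next
        orient[u] <- xor(orient[v] == 1L, nb[r, 2] == "1")
        orient[u] <- as.integer(orient[u])
        queue <- c(queue, u)
      }
    }
  }
  orient
}

#' Remove transitive edges
#'
#' Deletes exactly those edges `u -> v` for which a two-edge witness
#' `u -> w -> v` exists in the input graph (all such edges simultaneously,
#' witnesses taken from the original edge set). On a DAG this preserves
#' reachability.
#'
#' @param g A directed igraph.
#' @return The reduced graph.
#' @export
remove_transitive_edges <- function(g) {
  if (igraph::ecount(g) == 0) return(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1
  A2 <- A %*% A
  el <- igraph::as_edgelist(g, names = FALSE)
  witnessed <- as.vector(A2[el]) > 0
  igraph::delete_edges(g, which(witnessed))
}

# depth-first search from nodes in descending length order; returns the graph
# with cycles broken by repeatedly deleting the lowest-extension back edge
break_cycles <- function(g, max_iter = 1000L) {
  it <- 0L
  while (!igraph::is_dag(g) && it < max_iter) {
    it <- it + 1L
    n <- igraph::vcount(g)
    el <- igraph::as_edgelist(g, names = FALSE)
    ext <- igraph::E(g)$ext
    out_e <- split(seq_len(nrow(el)), factor(el[, 1], levels = seq_len(n)))
    color <- integer(n)
    backs <- integer(0)
    roots <- order(-igraph::V(g)$len, igraph::V(g)$name)
    for (s in roots) {
      if (color[s] != 0L) next
      stack_v <- s; stack_i <- 1L
      color[s] <- 1L
      while (length(stack_v) > 0) {
        v <- stack_v[length(stack_v)]
        i <- stack_i[length(stack_i)]
        ev <- out_e[[v]]
        if (i > length(ev)) {
          color[v] <- 2L
          stack_v <- stack_v[-length(stack_v)]
          stack_i <- stack_i[-length(stack_i)]
          next
        }
        stack_i[length(stack_i)] <- i + 1L
        e <- ev[i]
        wv <- el[e, 2]
        if (color[wv] == 1L) {
          backs <- c(backs, e)
        } else if (color[wv] == 0L) {
          color[wv] <- 1L
          stack_v <- c(stack_v, wv)
          stack_i <- c(stack_i, 1L)
        }
      }
    }
    if (length(backs) == 0) break
    drop <- backs[which.min(ext[backs])]
    g <- igraph::delete_edges(g, drop)
  }
  g
}

#' Longest path through a read overlap DAG
#'
#' Topological-order dynamic programming maximizing assembled bases: the score
#' of a path is the first node's length plus the sum of edge extension
#' weights. Cycles, which occur rarely (repeats, palindromes), are broken
#' first by deleting back edges found by depth-first search.
#'
#' @param g Overlap graph from [build_overlap_graph()].
#' @return Character vector of node ids along the best path (empty for an
#'   empty graph), with the score as attribute `score`.
#' @export
longest_path <- function(g) {
  if (igraph::vcount(g) == 0) return(character(0))
  g <- break_cycles(g)
  topo <- as.integer(igraph::topo_sort(g, mode = "out"))
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  ext <- igraph::E(g)$ext
  out_e <- split(seq_len(nrow(el)), factor(el[, 1], levels = seq_len(n)))
  score <- as.numeric(igraph::V(g)$len)
  parent <- rep(NA_integer_, n)
  for (v in topo) {
    for (e in out_e[[v]]) {
      w <- el[e, 2]
      s <- score[v] + ext[e]
      if (s > score[w]) {
        score[w] <- s
        parent[w] <- v
      }
    }
  }
  names_v <- igraph::V(g)$name
  best <- which(score == max(score))
  best <- best[order(names_v[best])][1]
  path <- integer(0)
  v <- best
  while (!is.na(v)) {
    path <- c(v, path)
    v <- parent[v]
  }
  structure(names_v[path], score = max(score))
}

rc_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

oriented_seq <- function(seq, orient) {
  if (isTRUE(orient == 1L)) rc_dna(seq) else seq
}

#' Concatenate a path of overlapping reads
#'
#' Builds the sequence spelled by a source-to-sink path: the first read in its
#' assigned orientation, then for each successor the unaligned suffix beyond
#' its overlap with the predecessor.
#'
#' @param path Node id vector (as from [longest_path()]).
#' @param g The overlap graph the path lives in.
#' @param reads Read tibble supplying the sequences.
#' @return A list with `sequence`, `source_path` and `orientations`, of class
#'   `adhoc_ref`.
#' @export
concat_path <- function(path, g, reads) {
  if (length(path) == 0) {
    return(structure(list(sequence = "", source_path = character(0),
                          orientations = integer(0)), class = "adhoc_ref"))
  }
  seqs <- setNames(reads$sequence, reads$id)
  orient <- setNames(igraph::V(g)$orient, igraph::V(g)$name)
  parts <- vector("list", length(path))
  parts[[1]] <- oriented_seq(seqs[[path[1]]], orient[[path[1]]])
  if (length(path) > 1) {
    cuts <- igraph::E(g)$cut
    for (i in 2:length(path)) {
      eid <- igraph::get_edge_ids(g, c(path[i - 1], path[i]))
      if (eid == 0) abort("path nodes are not joined by a graph edge")
      w_seq <- oriented_seq(seqs[[path[i]]], orient[[path[i]]])
      parts[[i]] <- substr(w_seq, cuts[eid] + 1L, nchar(w_seq))
    }
  }
  structure(list(sequence = paste0(unlist(parts), collapse = ""),
                 source_path = as.character(path),
                 orientations = unname(orient[path])),
            class = "adhoc_ref")
}

# graph -> transitive reduction -> longest path -> concatenation; the shared
# backbone-assembly step of local assembly, super read building and correction
assemble_longest_path <- function(reads, overlaps, params) {
  g <- build_overlap_graph(reads, overlaps, params)
  g <- remove_transitive_edges(g)
  path <- longest_path(g)
  if (length(path) == 0) {
    top <- reads[order(-reads$length, reads$id)[1], ]
    return(list(sequence = top$sequence, path = top$id, graph = g))
  }
  ref <- concat_path(path, g, reads)
  list(sequence = ref$sequence, path = ref$source_path, graph = g)
}
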