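# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately naive (enumeration, brute force) and never call the
# code paths they check.

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# reverse complement, independent of the package's implementation
rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

reads_tbl <- function(seqs, ids = sprintf("r%03d", seq_along(seqs))) {
  tibble::tibble(id = ids, sequence = toupper(seqs),
                 quality = NA_character_, length = nchar(seqs))
}

# error-free reads tiling a template left to right
tile_reads <- function(template, read_len, step, rc_every = 0) {
  starts <- seq(1, max(1, nchar(template) - read_len + 1), by = step)
  seqs <- substring(template, starts, pmin(nchar(template), starts + read_len - 1))
  if (rc_every > 0) {
    flip <- seq_along(seqs) %% rc_every == 0
    seqs[flip] <- vapply(seqs[flip], rc_oracle, character(1))
  }
  reads_tbl(seqs)
}

# substitute bases at random positions, fixed seed
mutate_seq <- function(s, rate, seed) {
  withr::with_seed(seed, {
    ch <- strsplit(s, "")[[1]]
    hit <- which(runif(length(ch)) < rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  })
}

make_allele_matrix <- function(m, w = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("r%02d", seq_len(nrow(m)))
  if (is.null(w)) w <- matrix(1, nrow(m), ncol(m), dimnames = dimnames(m))
  w[is.na(m)] <- NA_real_
  structure(list(m = m, w = w,
                 sites = tibble::tibble(position = seq_len(ncol(m)) - 1L)),
            class = "allele_matrix")
}

# exhaustive wMEC: enumerate all bipartitions of the rows
bf_wmec <- function(m, w = NULL) {
  if (is.null(w)) w <- matrix(1, nrow(m), ncol(m))
  n <- nrow(m)
  best <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    side <- c(0L, as.integer(intToBits(mask))[seq_len(n - 1)])
    cost <- 0
    for (j in seq_len(ncol(m))) {
      for (s in 0:1) {
        rows <- which(side == s & !is.na(m[, j]))
        if (length(rows) == 0) next
        w1 <- sum(w[rows, j][m[rows, j] == 1L])
        w0 <- sum(w[rows, j][m[rows, j] == 0L])
        cost <- cost + min(w0, w1)
      }
    }
    best <- min(best, cost)
  }
  best
}

# brute-force transitive reduction: scan every edge for a 2-step witness
bf_transitive_removed <- function(edges) {
  # edges: 2-column matrix of integer node ids
  has <- paste(edges[, 1], edges[, 2])
  removed <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges[i, 1]; v <- edges[i, 2]
    ws <- edges[edges[, 1] == u, 2]
    removed[i] <- any(paste(ws, v) %in% has & ws != v)
  }
  removed
}

# reachability matrix by repeated squaring of the adjacency
bf_reach <- function(edges, n) {
  A <- matrix(FALSE, n, n)
  A[edges] <- TRUE
  R <- A
  for (k in seq_len(n)) R <- R | (R %*% A > 0)
  R
}

# exhaustive longest path: score = first node length + sum of edge extensions
bf_longest_path_score <- function(nodes_len, edges, ext) {
  best <- max(nodes_len)
  grow <- function(path, score) {
    best <<- max(best, score)
    out <- which(edges[, 1] == path[length(path)])
    for (e in out) {
      v <- edges[e, 2]
      if (!(v %in% path)) grow(c(path, v), score + ext[e])
    }
  }
  for (s in seq_along(nodes_len)) grow(s, nodes_len[s])
  best
}

random_dag <- function(n, p_edge, seed) {
  withr::with_seed(seed, {
    perm <- sample.int(n)
    edges <- NULL
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p_edge) edges <- rbind(edges, c(perm[i], perm[j]))
      }
    }
    if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
    list(n = n, edges = edges,
         ext = if (nrow(edges)) sample.int(1000, nrow(edges), replace = TRUE)
               else integer(0),
         len = sample.int(5000, n, replace = TRUE))
  })
}

# igraph from a random DAG fixture, shaped like a build_overlap_graph() result
dag_to_graph <- function(d) {
  vertices <- data.frame(name = sprintf("n%02d", seq_len(d$n)),
                         len = d$len, orient = 0L)
  edges <- if (nrow(d$edges) > 0) {
    data.frame(from = sprintf("n%02d", d$edges[, 1]),
               to = sprintf("n%02d", d$edges[, 2]),
               ext = d$ext, cut = 0L, ovlen = 0L, identity = 1)
  } else {
    data.frame(from = character(0), to = character(0), ext = integer(0),
               cut = integer(0), ovlen = integer(0), identity = numeric(0))
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = vertices)
}

n50_oracle <- function(lengths, total = sum(lengths)) {
  s <- sort(lengths, decreasing = TRUE)
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= total / 2) return(x)
  }
  NA_integer_
}
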