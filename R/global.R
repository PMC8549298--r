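#' Build the super-read overlap graph
#'
#' Same construction as the read overlap graph, but over super reads and with
#' stricter thresholds (`sr_min_ovlp_len`, `sr_min_identity`): super reads
#' are long and near error-free, so near-perfect identity in the overlap is a
#' necessary condition for an edge. Super reads contained in other super
#' reads are absorbed (dropped from the graph; their ids are recorded in the
#' graph attribute `absorbed`).
#'
#' @param superreads Super-read tibble.
#' @param params [assembly_params()].
#' @param contain_frac A super read is also absorbed when a single overlap
#'   covers at least this fraction of its length at
#'   `sr_contain_identity` or better (near-containment): its possible
#'   extension is below the overlap scale and keeping it would emit a
#'   duplicate near-identical contig.
#' @return An igraph (see [build_overlap_graph()]).
#' @export
build_super_read_graph <- function(superreads, params = assembly_params(),
                                   contain_frac = 0.95) {
  sp <- params
  sp$min_ovlp_len <- params$sr_min_ovlp_len
  sp$min_identity <- params$sr_min_identity
  reads_tbl <- superreads[, c("id", "sequence", "length")]
  raw_ov <- compute_overlaps(reads_tbl, sp)
  ov <- classify_and_filter(raw_ov, sp, keep_containments = TRUE)
  # containment candidates are collected at the raw-read identity floor:
  # a redundant low-coverage super read can sit far below the edge identity
  lo <- sp
  lo$min_identity <- params$min_identity
  lo$min_ovlp_len <- params$min_ovlp_len
  ov_lo <- classify_and_filter(raw_ov, lo, keep_containments = TRUE)

  # near-containment absorption: the shorter super read of a high-identity
  # pair whose overlap spans almost all of it adds no usable extension
  near <- character(0)
  dov <- ov[grepl("dovetail", ov$olclass) &
              ov$identity >= params$sr_contain_identity, , drop = FALSE]
  if (nrow(dov) > 0) {
    for (i in seq_len(nrow(dov))) {
      qshorter <- dov$query_len[i] < dov$target_len[i] ||
        (dov$query_len[i] == dov$target_len[i] &&
           dov$query_id[i] > dov$target_id[i])
      short_len <- min(dov$query_len[i], dov$target_len[i])
      if (dov$block_len[i] >= contain_frac * short_len) {
        near <- c(near, if (qshorter) dov$query_id[i] else dov$target_id[i])
      }
    }
    near <- unique(near)
  }
  if (length(near) > 0) {
    reads_tbl <- reads_tbl[!reads_tbl$id %in% near, , drop = FALSE]
    ov <- ov[!(ov$query_id %in% near | ov$target_id %in% near), , drop = FALSE]
  }

  # remaining (near-)containment relations, kept as candidates for the
  # genotype-based absorption of redundant super reads
  ov_lo <- ov_lo[!(ov_lo$query_id %in% near | ov_lo$target_id %in% near), ,
                 drop = FALSE]
  cand <- containment_candidates(ov_lo, params$min_identity, contain_frac)

  g <- build_overlap_graph(reads_tbl, ov, sp,
                           contain_identity = params$sr_contain_identity)
  g <- igraph::set_graph_attr(g, "absorbed",
                              unique(c(igraph::graph_attr(g, "absorbed"),
                                       near)))
  igraph::set_graph_attr(g, "containment_candidates", cand)
}

# Heterozygosity test for super-read pairs, by group-consensus discordance.
# Each endpoint group's reads are mapped to the backbone; a position is
# heterozygous iff both groups have >= min_reads covering it, each group's
# top base carries >= min_frac of its own coverage, and the two top bases
# differ. Sequencing errors are i.i.d. *within* a group and essentially never
# give an 80%-consistent wrong base, while a true heterozygous site splits
# exactly along group lines — so the test stays valid at high read error
# rates where allele-fraction callers drown in error-pileup coincidences.
# Backbone errors cancel (both groups are compared to each other, not to the
# backbone), and a mixed (unphasable) group never reaches internal
# consistency, so a redundant mixed super read genotypes as homozygous.
count_group_discordant_sites <- function(ref, reads_a, reads_b,
                                         region_start, region_end, params,
                                         min_reads = 3L, min_frac = 0.8) {
  group_top <- function(grp_reads) {
    aln <- map_reads(ref, grp_reads, params)
    keep <- which(aln$tbl$ok)
    if (length(keep) == 0) return(NULL)
    counts <- cpp_base_counts(nchar(ref), aln$tbl$ref_start[keep],
                              aln$rows[keep])
    m <- t(counts[1:4, , drop = FALSE])
    cov <- rowSums(m)
    top <- max.col(m, ties.method = "first")
    list(cov = cov, top = top, frac = ifelse(cov > 0, m[cbind(seq_len(nrow(m)), top)] / cov, 0))
  }
  a <- group_top(reads_a)
  b <- group_top(reads_b)
  if (is.null(a) || is.null(b)) return(0L)
  pos <- seq_len(nchar(ref)) - 1L
  het <- a$cov >= min_reads & b$cov >= min_reads &
    a$frac >= min_frac & b$frac >= min_frac & a$top != b$top &
    pos >= region_start & pos < region_end
  sum(het)
}

# rows where one super read is contained, or nearly contained (overlap covers
# >= contain_frac of it), in another, at or above an identity floor
containment_candidates <- function(ov, min_identity, contain_frac,
                                   hang_slack = 0L) {
  out <- tibble(contained = character(), container = character(),
                c_start = integer(), c_end = integer(), identity = numeric(),
                block_len = integer())
  if (nrow(ov) == 0) return(out)
  short_len <- pmin(ov$query_len, ov$target_len)
  sel <- ov$identity >= min_identity &
    (ov$olclass %in% c("query_contained", "target_contained") |
       ov$block_len >= contain_frac * short_len |
       short_len - ov$block_len <= hang_slack)
  ov <- ov[sel, , drop = FALSE]
  if (nrow(ov) == 0) return(out)
  q_contained <- ifelse(ov$olclass == "query_contained", TRUE,
                        ifelse(ov$olclass == "target_contained", FALSE,
                               ov$query_len <= ov$target_len))
  tibble(
    contained = ifelse(q_contained, ov$query_id, ov$target_id),
    container = ifelse(q_contained, ov$target_id, ov$query_id),
    c_start = ifelse(q_contained, ov$target_start, ov$query_start),
    c_end = ifelse(q_contained, ov$target_end, ov$query_end),
    identity = ov$identity,
    block_len = ov$block_len
  )
}

#' Absorb redundant (near-)contained super reads
#'
#' A super read (nearly) contained in another adds little or no extension;
#' whether it adds *haplotype information* is decided here by genotyping the
#' containment region: both groups' raw reads are mapped onto the container,
#' and a site is heterozygous iff each group's internal consensus (at least
#' three reads, 80\% agreement) supports a different base. The contained
#' super read is absorbed iff at most `params$snp_filter_k` such sites are
#' found: a same-haplotype duplicate — or a mixed, unphasable leftover, whose
#' group never reaches internal consistency — genotypes homozygous, while a
#' true cross-haplotype containment genotypes heterozygous and is kept.
#'
#' Used by the pipeline when `snp_edge_filter` is on (it relies on the same
#' genotyping machinery and evidence reads).
#'
#' @param g Super-read graph from [build_super_read_graph()].
#' @param superreads Super-read tibble.
#' @param evidence_reads Tibble `sr_id`, `read_id`, `sequence` with each
#'   group's raw reads.
#' @param params [assembly_params()].
#' @return The graph with absorbed vertices removed (ids appended to the
#'   `absorbed` graph attribute).
#' @export
absorb_redundant_super_reads <- function(g, superreads, evidence_reads,
                                         params = assembly_params()) {
  cand <- igraph::graph_attr(g, "containment_candidates")
  if (is.null(cand) || nrow(cand) == 0) return(g)
  absorbed <- igraph::graph_attr(g, "absorbed") %||% character(0)
  len_of <- setNames(superreads$length, superreads$id)
  seq_of <- setNames(superreads$sequence, superreads$id)

  # process shortest contained super reads first
  for (cid in unique(cand$contained[order(len_of[cand$contained])])) {
    if (cid %in% absorbed || !cid %in% igraph::V(g)$name) next
    rows <- cand[cand$contained == cid & !(cand$container %in% absorbed), ,
                 drop = FALSE]
    rows <- rows[rows$container %in% igraph::V(g)$name, , drop = FALSE]
    if (nrow(rows) == 0) next
    best <- rows[which.max(rows$block_len), ]
    grp_a <- evidence_reads[evidence_reads$sr_id == best$container, ,
                            drop = FALSE]
    grp_b <- evidence_reads[evidence_reads$sr_id == cid, , drop = FALSE]
    shared <- intersect(grp_a$read_id, grp_b$read_id)
    grp_a <- grp_a[!grp_a$read_id %in% shared, , drop = FALSE]
    grp_b <- grp_b[!grp_b$read_id %in% shared, , drop = FALSE]
    as_reads <- function(g2) tibble(id = g2$read_id, sequence = g2$sequence,
                                    length = nchar(g2$sequence))
    absorb <- if (nrow(grp_a) == 0 || nrow(grp_b) == 0) {
      TRUE  # no discriminating reads: a duplicate of the same evidence
    } else {
      n_het <- count_group_discordant_sites(
        seq_of[[best$container]], as_reads(grp_a), as_reads(grp_b),
        best$c_start, best$c_end, params)
      n_het <= params$snp_filter_k
    }
    if (absorb) {
      g <- igraph::delete_vertices(g, cid)
      absorbed <- c(absorbed, cid)
    }
  }
  igraph::set_graph_attr(g, "absorbed", absorbed)
}

#' SNP-based spurious edge removal
#'
#' Cross-haplotype overlaps can look clean by identity alone. For every edge
#' the reads of both endpoint groups are mapped to the sequence formed by
#' concatenating the two super reads along their overlap, and the overlap
#' region is genotyped by group-consensus discordance: a site is heterozygous
#' iff each group's own pileup (at least three reads, 80\% internal
#' agreement) supports a different base — a test that stays valid at high
#' read error rates, where allele-fraction callers hit error-pileup
#' coincidences. The edge is removed iff more than `params$snp_filter_k`
#' heterozygous sites are found (default 0: any heterozygous site removes
#' the edge, i.e. a perfect overlap is required). Recommended for small
#' genomes or highly polymorphic regions.
#'
#' @param g Super-read overlap graph.
#' @param superreads Super-read tibble (sequences for the concatenation).
#' @param corrected_reads Tibble `sr_id`, `read_id`, `sequence` linking each
#'   super read to its group's (corrected) reads.
#' @param params [assembly_params()].
#' @return The filtered graph.
#' @export
remove_spurious_edges_by_snps <- function(g, superreads, corrected_reads,
                                          params = assembly_params()) {
  if (igraph::ecount(g) == 0) return(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  lens <- setNames(superreads$length, superreads$id)
  drop <- logical(nrow(el))
  for (e in seq_len(nrow(el))) {
    u <- el[e, 1]; v <- el[e, 2]
    junction <- concat_path(c(u, v), g, superreads)$sequence
    jl <- nchar(junction)
    ov_start <- jl - lens[[v]]           # 0-based overlap interval on junction
    ov_end <- lens[[u]]
    grp_u <- corrected_reads[corrected_reads$sr_id == u, , drop = FALSE]
    grp_v <- corrected_reads[corrected_reads$sr_id == v, , drop = FALSE]
    shared <- intersect(grp_u$read_id, grp_v$read_id)
    grp_u <- grp_u[!grp_u$read_id %in% shared, , drop = FALSE]
    grp_v <- grp_v[!grp_v$read_id %in% shared, , drop = FALSE]
    if (nrow(grp_u) == 0 || nrow(grp_v) == 0) next
    as_reads <- function(g2) tibble(id = g2$read_id, sequence = g2$sequence,
                                    length = nchar(g2$sequence))
    n_het <- count_group_discordant_sites(junction, as_reads(grp_u),
                                          as_reads(grp_v), ov_start, ov_end,
                                          params)
    drop[e] <- n_het > params$snp_filter_k
  }
  igraph::delete_edges(g, which(drop))
}

#' Remove tips from the super-read graph
#'
#' A tip is a dead-end branch of at most `params$tip_max_nodes` nodes hanging
#' off a branching node, on the source or the sink side; tips are likely to
#' be introduced by spurious overlaps. At every branch point, dead-end
#' branches within the node limit are deleted as long as a longer or
#' continuing sibling branch exists (if all competing branches are tips, the
#' longest survives), so the through-path is never mistaken for a tip.
#' Removal is applied iteratively to a fixed point. A plain path component
#' is not a tip (there is no branching node to hang off).
#'
#' @param g Directed overlap graph.
#' @param params [assembly_params()].
#' @return The simplified graph.
#' @export
remove_tips <- function(g, params = assembly_params()) {
  repeat {
    vs <- igraph::V(g)$name
    if (length(vs) == 0) return(g)
    el <- igraph::as_edgelist(g, names = TRUE)
    indeg <- table(factor(el[, 2], levels = vs))
    outdeg <- table(factor(el[, 1], levels = vs))
    pred <- split(el[, 1], factor(el[, 2], levels = vs))
    succ <- split(el[, 2], factor(el[, 1], levels = vs))

    # follow a chain of non-branching nodes; a branch is "open" when it
    # reaches a branching node or exceeds the tip length limit
    walk <- function(start, forward) {
      nodes <- character(0)
      cur <- start
      repeat {
        if (indeg[[cur]] > 1 || outdeg[[cur]] > 1) {
          return(list(nodes = nodes, open = TRUE))
        }
        nodes <- c(nodes, cur)
        if (length(nodes) > params$tip_max_nodes) {
          return(list(nodes = nodes, open = TRUE))
        }
        nxt <- if (forward) succ[[cur]] else pred[[cur]]
        if (length(nxt) == 0) return(list(nodes = nodes, open = FALSE))
        cur <- nxt[[1]]
      }
    }

    collect <- function(branch_starts, forward) {
      branches <- lapply(branch_starts, walk, forward = forward)
      is_tip <- vapply(branches, function(x) !x$open, logical(1))
      if (!any(is_tip)) return(character(0))
      if (!all(is_tip)) {
        return(unlist(lapply(branches[is_tip], `[[`, "nodes")))
      }
      # all competing branches dead-end within the limit: keep the best one
      lens <- vapply(branches, function(x) length(x$nodes), integer(1))
      first <- vapply(branches, function(x) x$nodes[1], character(1))
      keep <- order(-lens, first)[1]
      unlist(lapply(branches[-keep], `[[`, "nodes"))
    }

    tips <- character(0)
    for (b in vs[outdeg >= 2]) tips <- c(tips, collect(succ[[b]], TRUE))
    for (b in vs[indeg >= 2]) tips <- c(tips, collect(pred[[b]], FALSE))
    tips <- unique(tips)
    if (length(tips) == 0) return(g)
    g <- igraph::delete_vertices(g, tips)
  }
}

#' Merge simple paths into contigs
#'
#' Standard unitig merging: an edge `u -> v` joins its endpoints into the
#' same contig iff `u` has out-degree one and `v` has in-degree one; every
#' maximal such path — and every isolated node — becomes one contig, so the
#' contigs partition the surviving nodes. The contig sequence is the
#' overlap-aware concatenation of its super reads.
#'
#' @param g Simplified super-read graph (tips and transitive edges removed).
#' @param superreads Super-read tibble.
#' @return A contig tibble: `id`, `sequence`, `length`, `super_read_ids`
#'   (list column), `n_super_reads`.
#' @export
merge_simple_paths <- function(g, superreads) {
  vs <- igraph::V(g)$name
  if (length(vs) == 0) {
    return(tibble(id = character(), sequence = character(), length = integer(),
                  super_read_ids = list(), n_super_reads = integer()))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  indeg <- table(factor(el[, 2], levels = vs))
  outdeg <- table(factor(el[, 1], levels = vs))
  mergeable <- el[outdeg[el[, 1]] == 1 & indeg[el[, 2]] == 1, , drop = FALSE]
  nxt <- setNames(mergeable[, 2], mergeable[, 1])
  has_in <- vs %in% mergeable[, 2]
  names(has_in) <- vs

  paths <- list()
  seen <- character(0)
  for (v in vs[!has_in]) {
    path <- v
    cur <- v
    while (cur %in% names(nxt)) {
      cur <- nxt[[cur]]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1]] <- path
    seen <- c(seen, path)
  }
  # perfect cycles (every node in/out-degree one) have no start node: break
  # each at its smallest id
  left <- setdiff(vs, seen)
  while (length(left) > 0) {
    start <- sort(left)[1]
    path <- start
    cur <- start
    while (cur %in% names(nxt) && !(nxt[[cur]] %in% path)) {
      cur <- nxt[[cur]]
      path <- c(path, cur)
    }
    paths[[length(paths) + 1]] <- path
    left <- setdiff(left, path)
  }
  # deterministic contig order: by first super read id
  paths <- paths[order(vapply(paths, `[[`, character(1), 1))]

  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    seqv <- if (length(p) == 1) {
      ors <- setNames(igraph::V(g)$orient, igraph::V(g)$name)
      oriented_seq(superreads$sequence[superreads$id == p], ors[[p]])
    } else {
      concat_path(p, g, superreads)$sequence
    }
    out[[i]] <- tibble(id = sprintf("contig_%d", i), sequence = seqv,
                       length = nchar(seqv), super_read_ids = list(p),
                       n_super_reads = length(p))
  }
  dplyr::bind_rows(out)
}

# Contig-level pass of the genotype-based absorption: a leftover super read
# that straddles the junction of two merged super reads is contained in no
# single super read, but it is contained in the merged contig. Same decision
# rule as absorb_redundant_super_reads(), with each contig's evidence being
# the union of its groups' raw reads.
absorb_redundant_contigs <- function(contigs, evidence_reads,
                                     params = assembly_params(),
                                     contain_frac = 0.95) {
  if (nrow(contigs) < 2) return(contigs)
  ov <- classify_and_filter(
    compute_overlaps(contigs[, c("id", "sequence", "length")], params),
    params, keep_containments = TRUE)
  # at this stage chain neighbours are already merged, so a dovetail partner
  # whose overhang is below the max_hang slack adds no meaningful extension
  cand <- containment_candidates(ov, params$min_identity, contain_frac,
                                 hang_slack = params$max_hang)
  if (nrow(cand) == 0) return(contigs)
  len_of <- setNames(contigs$length, contigs$id)
  grp_for <- function(cid) {
    srs <- unlist(contigs$super_read_ids[contigs$id == cid])
    g2 <- evidence_reads[evidence_reads$sr_id %in% srs, , drop = FALSE]
    g2 <- dplyr::distinct(g2, .data$read_id, .keep_all = TRUE)
    tibble(id = g2$read_id, sequence = g2$sequence,
           length = nchar(g2$sequence))
  }
  dropped <- character(0)
  for (cid in unique(cand$contained[order(len_of[cand$contained])])) {
    if (cid %in% dropped) next
    rows <- cand[cand$contained == cid & !(cand$container %in% dropped), ,
                 drop = FALSE]
    if (nrow(rows) == 0) next
    best <- rows[which.max(rows$block_len), ]
    grp_b <- grp_for(cid)
    grp_a <- grp_for(best$container)
    shared <- intersect(grp_a$id, grp_b$id)
    grp_a <- grp_a[!grp_a$id %in% shared, , drop = FALSE]
    grp_b <- grp_b[!grp_b$id %in% shared, , drop = FALSE]
    drop_it <- if (nrow(grp_a) == 0 || nrow(grp_b) == 0) {
      TRUE
    } else {
      ref <- contigs$sequence[contigs$id == best$container]
      count_group_discordant_sites(ref, grp_a, grp_b, best$c_start,
                                   best$c_end, params) <= params$snp_filter_k
    }
    if (drop_it) dropped <- c(dropped, cid)
  }
  contigs[!contigs$id %in% dropped, , drop = FALSE]
}

#' Polish final contigs
#'
#' Pileup consensus of each contig from the corrected reads of its
#' constituent groups, recommended when the per-haplotype sequencing coverage
#' is below about 20x (super-read ends carry elevated error rates).
#' Contigs shorter than `params$min_contig_len` (default 1000 bp) are
#' dropped from the final output.
#'
#' @param contigs Contig tibble.
#' @param corrected_reads Tibble `sr_id`, `read_id`, `sequence`.
#' @param params [assembly_params()].
#' @param do_polish Set `FALSE` to only apply the length filter.
#' @return The polished, length-filtered contig tibble.
#' @export
polish_contigs <- function(contigs, corrected_reads, params = assembly_params(),
                           do_polish = TRUE) {
  if (nrow(contigs) > 0 && do_polish) {
    for (i in seq_len(nrow(contigs))) {
      grp <- corrected_reads[corrected_reads$sr_id %in%
                               contigs$super_read_ids[[i]], , drop = FALSE]
      grp <- dplyr::distinct(grp, .data$read_id, .keep_all = TRUE)
      if (nrow(grp) == 0) next
      grp_reads <- tibble(id = grp$read_id, sequence = grp$sequence,
                          length = nchar(grp$sequence))
      pol <- polish(contigs$sequence[i], grp_reads, params)
      contigs$sequence[i] <- as.character(pol)
      contigs$length[i] <- nchar(pol)
    }
  }
  contigs[contigs$length >= params$min_contig_len, , drop = FALSE]
}
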