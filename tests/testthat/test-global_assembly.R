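p_hifi <- assembly_params("hifi")

# two haplotypes over a long region, error-free super reads from tiling blocks
sr_fixture <- function(hap_len = 50000, n_snps = 500, block = 14000,
                       step = 9000, seed = 121) {
  withr::with_seed(seed, {
    h1 <- random_dna(hap_len)
    ch <- strsplit(h1, "")[[1]]
    pos <- sort(sample(seq(50, hap_len - 50), n_snps))
    for (q in pos) ch[q] <- setdiff(c("A", "C", "G", "T"), ch[q])[1]
    h2 <- paste(ch, collapse = "")
  })
  srs <- list()
  k <- 0
  for (hap in 1:2) {
    hs <- if (hap == 1) h1 else h2
    starts <- seq(1, hap_len - block + 1, by = step)
    for (s in starts) {
      k <- k + 1
      seqv <- substr(hs, s, s + block - 1)
      srs[[k]] <- tibble::tibble(
        id = sprintf("sr_c%d_p%d", length(starts) * (hap - 1) + match(s, starts), hap),
        cluster_id = match(s, starts), phase = hap,
        sequence = seqv, length = nchar(seqv),
        coverage = list(rep(10L, nchar(seqv))),
        constituent_ids = list(sprintf("rd%03d", k)), n_reads = 5L)
    }
  }
  list(h1 = h1, h2 = h2, superreads = dplyr::bind_rows(srs))
}

test_that("same-haplotype super reads connect; low-identity overlaps do not", {
  fx <- sr_fixture()
  g <- build_super_read_graph(fx$superreads, p_hifi)
  el <- igraph::as_edgelist(g)
  expect_gt(nrow(el), 0)
  phase_of <- function(id) fx$superreads$phase[fx$superreads$id == id]
  # identity >= 0.98 admits both same- and cross-haplotype edges here (1% het),
  # but every same-haplotype adjacency must be present
  same <- mapply(function(a, b) phase_of(a) == phase_of(b), el[, 1], el[, 2])
  expect_gt(sum(same), 0)
  # each haplotype's nodes form a connected chain through same-phase edges
  for (hap in 1:2) {
    ids <- fx$superreads$id[fx$superreads$phase == hap]
    sub <- igraph::induced_subgraph(g, ids)
    expect_true(igraph::is_connected(sub, mode = "weak"))
  }
  # a 0.90-identity overlap is below the strict threshold: no edge
  a <- random_dna(8000, seed = 122)
  b <- paste0(mutate_seq(substr(a, 4001, 8000), 0.10, seed = 123),
              random_dna(4000, seed = 124))
  two <- tibble::tibble(id = c("s1", "s2"), sequence = c(a, b),
                        length = 8000L)
  g2 <- build_super_read_graph(
    dplyr::mutate(two, cluster_id = 1:2, phase = 1L,
                  coverage = list(rep(5L, 8000), rep(5L, 8000)),
                  constituent_ids = list("x", "y"), n_reads = 1L), p_hifi)
  expect_equal(igraph::ecount(g2), 0L)
  # a single super read: one isolated node
  g3 <- build_super_read_graph(fx$superreads[1, ], p_hifi)
  expect_equal(igraph::vcount(g3), 1L)
})

test_that("SNP-based filtering removes cross-haplotype edges, keeps clean ones", {
  fx <- sr_fixture(hap_len = 30000, n_snps = 300, block = 12000, step = 7000)
  srs <- fx$superreads
  g <- build_super_read_graph(srs, p_hifi)
  el <- igraph::as_edgelist(g)
  phase_of <- function(id) srs$phase[srs$id == id]
  cross_before <- sum(mapply(function(a, b) phase_of(a) != phase_of(b),
                             el[, 1], el[, 2]))
  expect_gt(cross_before, 0)  # cross-hap overlaps pass the identity bar alone

  # constituent reads: error-free tiles of the right haplotype region,
  # dense enough that both groups cover the overlap interior at >= 3 reads
  corr <- list()
  for (i in seq_len(nrow(srs))) {
    tiles <- tile_reads(srs$sequence[i], 4000, 500)
    corr[[i]] <- tibble::tibble(sr_id = srs$id[i],
                                read_id = paste0(srs$id[i], "_", tiles$id),
                                sequence = tiles$sequence)
  }
  corr <- dplyr::bind_rows(corr)
  g2 <- remove_spurious_edges_by_snps(g, srs, corr, p_hifi)
  el2 <- igraph::as_edgelist(g2)
  cross_after <- sum(mapply(function(a, b) phase_of(a) != phase_of(b),
                            el2[, 1], el2[, 2]))
  same_after <- sum(mapply(function(a, b) phase_of(a) == phase_of(b),
                           el2[, 1], el2[, 2]))
  expect_equal(cross_after, 0L)   # k=0: any het site kills the edge
  expect_gt(same_after, 0L)       # within-haplotype edges survive

  # threshold semantics: with k large enough, cross edges survive
  p_loose <- p_hifi
  p_loose$snp_filter_k <- 1000L
  g3 <- remove_spurious_edges_by_snps(g, srs, corr, p_loose)
  expect_equal(igraph::ecount(g3), igraph::ecount(g))
})

test_that("tip removal deletes short dead ends and spares pure paths", {
  mk <- function(edges, n) {
    dag_to_graph(list(n = n, edges = edges,
                      ext = rep(10L, nrow(edges)),
                      len = rep(100L, n)))
  }
  # main path 1-2-3-4 with a 1-node dead end off node 2
  g <- mk(rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5)), 5)
  out <- remove_tips(g, p_hifi)
  expect_setequal(igraph::V(out)$name, sprintf("n%02d", 1:4))

  # pure path: unchanged
  g2 <- mk(rbind(c(1, 2), c(2, 3)), 3)
  expect_equal(igraph::vcount(remove_tips(g2, p_hifi)), 3L)

  # 2-node tip removed at tip_max_nodes = 2 off a longer main path;
  # a 3-node dead-end branch exceeds the limit and is retained
  g3 <- mk(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 6), c(6, 7)), 7)
  out3 <- remove_tips(g3, p_hifi)
  expect_setequal(igraph::V(out3)$name, sprintf("n%02d", 1:5))
  g4 <- mk(rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(2, 6), c(6, 7), c(7, 8)), 8)
  expect_equal(igraph::vcount(remove_tips(g4, p_hifi)), 8L)

  # source-side tip
  g5 <- mk(rbind(c(5, 2), c(1, 2), c(2, 3), c(3, 4)), 5)
  out5 <- remove_tips(g5, p_hifi)
  expect_equal(igraph::vcount(out5), 4L)
})

test_that("simple-path merging partitions nodes and counts paths", {
  seqs <- setNames(lapply(1:6, function(i) random_dna(3000, seed = 130 + i)),
                   sprintf("n%02d", 1:6))
  mk_srs <- function(ids) {
    tibble::tibble(id = ids, cluster_id = 1L, phase = 1L,
                   sequence = unname(unlist(seqs[ids])), length = 3000L,
                   coverage = lapply(ids, function(x) rep(5L, 3000)),
                   constituent_ids = as.list(ids), n_reads = 1L)
  }
  mk <- function(edges, ids) {
    vertices <- data.frame(name = ids, len = 3000L, orient = 0L)
    edges_df <- if (nrow(edges) > 0) {
      data.frame(from = ids[edges[, 1]], to = ids[edges[, 2]],
                 ext = 1500L, cut = 1500L, ovlen = 1500L, identity = 1)
    } else {
      data.frame(from = character(0), to = character(0), ext = integer(0),
                 cut = integer(0), ovlen = integer(0), identity = numeric(0))
    }
    igraph::graph_from_data_frame(edges_df, directed = TRUE,
                                  vertices = vertices)
  }
  # chain of 3 -> one contig covering all nodes
  ids3 <- sprintf("n%02d", 1:3)
  ct <- merge_simple_paths(mk(rbind(c(1, 2), c(2, 3)), ids3), mk_srs(ids3))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$n_super_reads, 3L)
  expect_equal(ct$length, 3000L + 1500L + 1500L)

  # X shape: 2 in, 2 out of a hub -> 5 contigs, nodes partitioned
  ids5 <- sprintf("n%02d", 1:5)
  x <- mk(rbind(c(1, 3), c(2, 3), c(3, 4), c(3, 5)), ids5)
  ctx <- merge_simple_paths(x, mk_srs(ids5))
  expect_equal(nrow(ctx), 5L)
  expect_setequal(unlist(ctx$super_read_ids), ids5)
  expect_equal(anyDuplicated(unlist(ctx$super_read_ids)), 0L)

  # isolated node -> contig equal to that super read
  iso <- mk(matrix(integer(0), 0, 2), "n06")
  cti <- merge_simple_paths(iso, mk_srs("n06"))
  expect_equal(cti$sequence, seqs[["n06"]])

  # empty graph -> no contigs
  e <- igraph::make_empty_graph(directed = TRUE)
  expect_equal(nrow(merge_simple_paths(e, mk_srs(ids3)[0, ])), 0L)
})

test_that("contig polishing repairs end errors and applies the length floor", {
  tpl <- random_dna(6000, seed = 141)
  reads <- tile_reads(tpl, 1500, 100)  # ~15x
  corr <- tibble::tibble(sr_id = "sr_a", read_id = reads$id,
                         sequence = reads$sequence)
  # 2 seeded errors in a super-read end region (contig interior, well covered)
  broken <- paste0(substr(tpl, 1, 1999),
                   chartr("ACGT", "TGCA", substr(tpl, 2000, 2001)),
                   substr(tpl, 2002, 6000))
  expect_false(broken == tpl)
  contigs <- tibble::tibble(id = "contig_1", sequence = broken,
                            length = 6000L, super_read_ids = list("sr_a"),
                            n_super_reads = 1L)
  out <- polish_contigs(contigs, corr, p_hifi)
  expect_equal(out$sequence, tpl)

  # 900 bp contig dropped from the final output
  short <- tibble::tibble(id = "c2", sequence = random_dna(900, 142),
                          length = 900L, super_read_ids = list("sr_b"),
                          n_super_reads = 1L)
  expect_equal(nrow(polish_contigs(short, corr[0, ], p_hifi)), 0L)

  # error-free contig unchanged
  clean <- tibble::tibble(id = "c3", sequence = tpl, length = 6000L,
                          super_read_ids = list("sr_a"), n_super_reads = 1L)
  expect_equal(polish_contigs(clean, corr, p_hifi)$sequence, tpl)
})
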