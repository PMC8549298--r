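p_hifi <- assembly_params("hifi")

graph_fixture <- function(template, read_len, step, rc_every = 0) {
  rd <- tile_reads(template, read_len, step, rc_every = rc_every)
  ov <- classify_and_filter(compute_overlaps(rd, p_hifi), p_hifi,
                            keep_containments = TRUE)
  list(reads = rd, ov = ov,
       graph = build_overlap_graph(rd, ov, p_hifi))
}

test_that("tiled reads give a path-shaped overlap graph", {
  fx <- graph_fixture(random_dna(6000, seed = 71), 3000, 1500)
  g <- fx$graph
  expect_equal(igraph::vcount(g), 3L)
  g2 <- remove_transitive_edges(g)
  expect_equal(igraph::ecount(g2), 2L)
  deg_in <- igraph::degree(g2, mode = "in")
  deg_out <- igraph::degree(g2, mode = "out")
  expect_equal(sum(deg_in == 0), 1L)   # unique source
  expect_equal(sum(deg_out == 0), 1L)  # unique sink
})

test_that("a single read yields a single node and itself as path", {
  rd <- reads_tbl(random_dna(2000, seed = 72))
  g <- build_overlap_graph(rd, classify_and_filter(compute_overlaps(rd, p_hifi),
                                                   p_hifi), p_hifi)
  expect_equal(igraph::vcount(g), 1L)
  expect_equal(igraph::ecount(g), 0L)
  path <- longest_path(g)
  expect_equal(as.character(path), rd$id)
  expect_equal(attr(path, "score"), 2000)
})

test_that("the longest path orders error-free tiled reads by true offset", {
  # 5 reads with 50% overlap from a 6 kb template (some reverse-complemented)
  fx <- graph_fixture(random_dna(6000, seed = 73), 2000, 1000, rc_every = 2)
  path <- longest_path(remove_transitive_edges(fx$graph))
  expect_equal(as.character(path), sprintf("r%03d", 1:5))
})

test_that("transitive reduction matches the brute-force witness scan", {
  # triangle: the shortcut edge has a witness, the others do not
  tri <- dag_to_graph(list(n = 3, edges = rbind(c(1, 2), c(2, 3), c(1, 3)),
                           ext = c(10L, 10L, 20L), len = c(100L, 90L, 80L)))
  red <- remove_transitive_edges(tri)
  el <- igraph::as_edgelist(red)
  expect_equal(nrow(el), 2L)
  expect_false(any(el[, 1] == "n01" & el[, 2] == "n03"))

  # chain unchanged
  ch <- dag_to_graph(list(n = 4, edges = rbind(c(1, 2), c(2, 3), c(3, 4)),
                          ext = rep(5L, 3), len = rep(50L, 4)))
  expect_equal(igraph::ecount(remove_transitive_edges(ch)), 3L)

  # random DAGs vs the oracle, with reachability preserved
  for (seed in 1:100) {
    d <- random_dag(n = sample(4:12, 1), p_edge = 0.35, seed = seed)
    if (nrow(d$edges) == 0) next
    g <- dag_to_graph(d)
    red <- remove_transitive_edges(g)
    removed_oracle <- bf_transitive_removed(d$edges)
    expect_equal(igraph::ecount(red), sum(!removed_oracle))
    kept <- igraph::as_edgelist(red)
    kept_ids <- cbind(as.integer(sub("n", "", kept[, 1])),
                      as.integer(sub("n", "", kept[, 2])))
    oracle_kept <- d$edges[!removed_oracle, , drop = FALSE]
    expect_equal(kept_ids[order(kept_ids[, 1], kept_ids[, 2]), , drop = FALSE],
                 oracle_kept[order(oracle_kept[, 1], oracle_kept[, 2]), ,
                             drop = FALSE], ignore_attr = TRUE)
    expect_equal(bf_reach(kept_ids, d$n), bf_reach(d$edges, d$n))
  }
})

test_that("longest path equals exhaustive enumeration on random DAGs", {
  for (seed in 101:130) {
    d <- random_dag(n = sample(4:10, 1), p_edge = 0.3, seed = seed)
    g <- dag_to_graph(d)
    path <- longest_path(g)
    expect_equal(attr(path, "score"),
                 bf_longest_path_score(d$len, d$edges, d$ext))
  }
})

test_that("parallel branches resolve to the heavier one", {
  d <- list(n = 4, edges = rbind(c(1, 2), c(2, 4), c(1, 3), c(3, 4)),
            ext = c(2000L, 2000L, 3500L, 3500L), len = rep(1000L, 4))
  path <- longest_path(dag_to_graph(d))
  expect_equal(as.character(path), c("n01", "n03", "n04"))
  expect_equal(attr(path, "score"), 1000 + 3500 + 3500)
})

test_that("concatenating a path reconstructs the template exactly", {
  tpl <- random_dna(6000, seed = 74)
  fx <- graph_fixture(tpl, 2000, 1000, rc_every = 2)
  g <- remove_transitive_edges(fx$graph)
  ref <- concat_path(longest_path(g), g, fx$reads)
  expect_equal(ref$sequence, tpl)

  # a single-read path is the read itself
  rd1 <- reads_tbl(random_dna(1500, seed = 75))
  g1 <- build_overlap_graph(rd1, classify_and_filter(
    compute_overlaps(rd1, p_hifi), p_hifi), p_hifi)
  expect_equal(concat_path(longest_path(g1), g1, rd1)$sequence, rd1$sequence)
})

test_that("polishing is a fixed point on error-free data and fixes errors", {
  tpl <- random_dna(4000, seed = 81)
  rd <- tile_reads(tpl, 1500, 200)
  pol <- polish(tpl, rd, p_hifi, rounds = 1)
  expect_equal(as.character(pol), tpl)

  # single substitution at 20x error-free cover is corrected unanimously
  broken <- paste0(substr(tpl, 1, 1999),
                   setdiff(c("A", "C", "G", "T"), substr(tpl, 2000, 2000))[1],
                   substr(tpl, 2001, 4000))
  fixed <- polish(broken, rd, p_hifi, rounds = 1)
  expect_equal(as.character(fixed), tpl)
})

test_that("polishing converges to the template on noisy reads", {
  p_clr <- assembly_params("clr")
  tpl <- random_dna(5000, seed = 82)
  rd <- tile_reads(tpl, 1200, 160)  # ~30x
  rd$sequence <- vapply(seq_len(nrow(rd)), function(i) {
    mutate_seq(rd$sequence[i], 0.02, seed = 8200 + i)
  }, character(1))
  rd$length <- nchar(rd$sequence)
  start <- mutate_seq(tpl, 0.02, seed = 8400)
  pol <- as.character(polish(start, rd, p_clr, rounds = 2))
  d <- utils::adist(pol, tpl)[1, 1]
  expect_lt(d / nchar(tpl), 0.005)  # >= 99.5% identity
  # polishing never increased the distance to the truth
  expect_lte(d, utils::adist(start, tpl)[1, 1])
})
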