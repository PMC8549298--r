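p_hifi <- assembly_params("hifi")
p_clr <- assembly_params("clr")

test_that("correction leaves error-free groups and singletons unchanged", {
  tpl <- random_dna(6000, seed = 111)
  rd <- tile_reads(tpl, 2000, 400)
  out <- correct_group_reads(rd, p_clr)
  expect_equal(out$sequence, rd$sequence)
  one <- rd[1, ]
  expect_equal(correct_group_reads(one, p_clr)$sequence, one$sequence)
})

test_that("correction reduces the error rate of a noisy group", {
  tpl <- random_dna(5000, seed = 112)
  rd <- tile_reads(tpl, 1800, 360)  # ~14 reads, ~5x... densify below
  rd <- dplyr::bind_rows(rd, tile_reads(tpl, 1800, 450))
  rd$id <- sprintf("n%03d", seq_len(nrow(rd)))
  noisy <- rd
  noisy$sequence <- vapply(seq_len(nrow(rd)), function(i) {
    mutate_seq(rd$sequence[i], 0.10, seed = 9000 + i)
  }, character(1))
  noisy$length <- nchar(noisy$sequence)
  corr <- correct_group_reads(noisy, p_clr)
  err <- function(x) {
    mean(vapply(seq_len(nrow(x)), function(i) {
      utils::adist(x$sequence[i], rd$sequence[i])[1, 1] / rd$length[i]
    }, numeric(1)))
  }
  expect_gt(err(noisy), 0.08)
  expect_lte(err(corr), 0.02)
})

test_that("a single-read group becomes a super read equal to the read", {
  rd <- reads_tbl(random_dna(2500, seed = 113))
  sr <- build_super_read(rd, p_hifi, cluster_id = 3L, phase = 0L)
  expect_equal(sr$sequence, rd$sequence)
  expect_equal(sr$phase, 0L)
  expect_equal(sr$constituent_ids[[1]], rd$id)
})

test_that("an error-free phased group assembles into an exact substring", {
  tpl <- random_dna(20000, seed = 114)
  rd <- tile_reads(tpl, 5000, 1500, rc_every = 3)
  sr <- build_super_read(rd, p_hifi, cluster_id = 1L, phase = 1L)
  expect_equal(nrow(sr), 1L)
  expect_true(grepl(sr$sequence, tpl, fixed = TRUE) ||
                grepl(rc_oracle(sr$sequence), tpl, fixed = TRUE))
  expect_gte(sr$length, 19000L)
  expect_equal(length(sr$coverage[[1]]), sr$length)
})

test_that("trimming keeps the longest coverage>=2 interval", {
  sr <- tibble::tibble(
    id = "sr_x", cluster_id = 1L, phase = 1L,
    sequence = strrep("A", 6000), length = 6000L,
    coverage = list(c(rep(1L, 1000), rep(1L, 1000), rep(5L, 3000), rep(1L, 1000))),
    constituent_ids = list("r1"), n_reads = 3L
  )
  out <- trim_super_read(sr, p_hifi)
  expect_equal(out$length, 3000L)
  expect_true(all(out$coverage[[1]] >= 2))

  # uniform high coverage: unchanged
  sr$coverage <- list(rep(10L, 6000))
  expect_equal(trim_super_read(sr, p_hifi)$length, 6000L)

  # all coverage 1: discarded
  sr$coverage <- list(rep(1L, 6000))
  expect_equal(nrow(trim_super_read(sr, p_hifi)), 0L)

  # interval shorter than the minimum overlap length: discarded
  sr$coverage <- list(c(rep(1L, 2800), rep(3L, 500), rep(1L, 2700)))
  expect_equal(nrow(trim_super_read(sr, p_hifi)), 0L)
})

test_that("a cluster yields two super reads with het sites, one without", {
  # diploid cluster: reads from two haplotypes differing at evenly spaced
  # SNPs, dense enough that every read covers a called site
  withr::with_seed(115, {
    h1 <- random_dna(8000)
    ch <- strsplit(h1, "")[[1]]
    pos <- seq(400, 7700, by = 480)
    for (q in pos) ch[q] <- setdiff(c("A", "C", "G", "T"), ch[q])[1]
    h2 <- paste(ch, collapse = "")
  })
  r1 <- tile_reads(h1, 2500, 250); r1$id <- sub("^r", "a", r1$id)
  r2 <- tile_reads(h2, 2500, 250); r2$id <- sub("^r", "b", r2$id)
  members <- dplyr::bind_rows(r1, r2)
  ov <- classify_and_filter(compute_overlaps(members, p_hifi), p_hifi,
                            keep_containments = TRUE)
  res <- haplobook:::process_cluster(members, ov, p_hifi, cluster_id = 1L)
  expect_equal(nrow(res$super_reads), 2L)
  expect_setequal(res$super_reads$phase, c(1L, 2L))
  # phased groups separate the haplotypes
  expect_equal(res$stats$n_both, 0L)
  for (i in 1:2) {
    sr <- res$super_reads[i, ]
    ok1 <- grepl(sr$sequence, h1, fixed = TRUE)
    ok2 <- grepl(sr$sequence, h2, fixed = TRUE)
    expect_true(xor(ok1, ok2))
  }
  # 'both' reads appear in the constituents of both super reads
  both_ids <- intersect(res$super_reads$constituent_ids[[1]],
                        res$super_reads$constituent_ids[[2]])
  expect_equal(sort(unique(c(res$super_reads$constituent_ids[[1]],
                             res$super_reads$constituent_ids[[2]]))),
               sort(members$id))

  # homozygous cluster: a single unphased super read
  same <- dplyr::bind_rows(r1, {
    x <- tile_reads(h1, 2500, 250); x$id <- sub("^r", "c", x$id); x
  })
  ov2 <- classify_and_filter(compute_overlaps(same, p_hifi), p_hifi,
                             keep_containments = TRUE)
  res2 <- haplobook:::process_cluster(same, ov2, p_hifi, cluster_id = 2L)
  expect_equal(nrow(res2$super_reads), 1L)
  expect_equal(res2$super_reads$phase, 0L)
})

test_that("hifi mode skips correction by default", {
  expect_false(assembly_params("hifi")$correct_raw_reads)
  expect_true(assembly_params("clr")$correct_raw_reads)
  expect_true(assembly_params("ont")$correct_raw_reads)
})
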