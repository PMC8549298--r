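p_hifi <- assembly_params("hifi")

# diploid cluster fixture: reads tiling two haplotypes differing at SNPs
phasing_fixture <- function(hap_len = 6000, n_snps = 12, read_len = 1500,
                            step = 300, seed = 7) {
  withr::with_seed(seed, {
    h1 <- random_dna(hap_len)
    pos <- sort(sample(seq(100, hap_len - 100), n_snps))
    ch <- strsplit(h1, "")[[1]]
    ch2 <- ch
    for (p in pos) ch2[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
    h2 <- paste(ch2, collapse = "")
    r1 <- tile_reads(h1, read_len, step)
    r1$id <- sub("^r", "a", r1$id)
    r2 <- tile_reads(h2, read_len, step)
    r2$id <- sub("^r", "b", r2$id)
    list(h1 = h1, h2 = h2, pos = pos, reads = dplyr::bind_rows(r1, r2))
  })
}

test_that("no sites are called on reads from identical haplotypes", {
  tpl <- random_dna(4000, seed = 91)
  rd <- tile_reads(tpl, 1200, 100)
  aln <- map_reads(tpl, rd, p_hifi)
  expect_equal(nrow(call_snps(aln, tpl, p_hifi)), 0L)
})

test_that("a balanced het site is called with af 0.5; thin data is not", {
  fx <- phasing_fixture(hap_len = 3000, n_snps = 1, read_len = 2800, step = 20)
  ref <- fx$h1
  aln <- map_reads(ref, fx$reads, p_hifi)
  sites <- call_snps(aln, ref, p_hifi)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$position, fx$pos - 1L)
  expect_equal(sites$af, 0.5, tolerance = 0.1)

  # 3 reads total: depth below 10, nothing called
  thin <- fx$reads[c(1, 2, nrow(fx$reads)), ]
  aln3 <- map_reads(ref, thin, p_hifi)
  expect_equal(nrow(call_snps(aln3, ref, p_hifi)), 0L)
})

test_that("the allele matrix encodes ref/alt/missing correctly", {
  fx <- phasing_fixture(hap_len = 5000, n_snps = 4, read_len = 4500, step = 50,
                        seed = 13)
  ref <- fx$h1
  aln <- map_reads(ref, fx$reads, p_hifi)
  sites <- call_snps(aln, ref, p_hifi)
  expect_equal(nrow(sites), 4L)
  am <- build_allele_matrix(aln, sites)
  # cell-by-cell: haplotype-1 reads carry 0, haplotype-2 reads carry 1
  for (i in seq_len(nrow(am$m))) {
    rid <- rownames(am$m)[i]
    expected <- if (startsWith(rid, "a")) 0L else 1L
    vals <- am$m[i, !is.na(am$m[i, ])]
    expect_true(all(vals == expected))
  }
  # a read covering no site gives an all-missing row
  far <- reads_tbl(substr(ref, 1, 60), ids = "tiny")
  aln2 <- map_reads(ref, dplyr::bind_rows(fx$reads, far), p_hifi)
  am2 <- build_allele_matrix(aln2, sites)
  expect_true(all(is.na(am2$m["tiny", ])))
  # weights are positive wherever an entry exists
  expect_true(all(am$w[!is.na(am$m)] > 0))
})

test_that("wMEC solves clean complementary rows at cost zero", {
  m <- matrix(c(0L, 1L, 0L, 1L,
                0L, 1L, 0L, 1L,
                1L, 0L, 1L, 0L,
                1L, 0L, 1L, 0L), 4, 4, byrow = TRUE)
  ph <- solve_wmec(make_allele_matrix(m), p_hifi)
  expect_equal(ph$mec_cost, 0)
  a <- ph$assignment
  expect_equal(a$haplotype[1], a$haplotype[2])
  expect_equal(a$haplotype[3], a$haplotype[4])
  expect_false(a$haplotype[1] == a$haplotype[3])
  expect_equal(a$haplotype[1], "H1")  # canonical: H1 holds the smallest id
})

test_that("a single column is always satisfiable at cost zero", {
  m <- matrix(c(0L, 0L, 1L), 3, 1)
  ph <- solve_wmec(make_allele_matrix(m), p_hifi)
  expect_equal(ph$mec_cost, 0)
})

test_that("wMEC equals exhaustive bipartition search on random instances", {
  withr::with_seed(4242, {
    for (trial in 1:100) {
      n <- sample(3:10, 1)
      s <- sample(2:8, 1)
      m <- matrix(sample(c(0L, 1L), n * s, replace = TRUE), n, s)
      # random missingness
      m[runif(n * s) < 0.2] <- NA_integer_
      w <- matrix(sample(1:30, n * s, replace = TRUE), n, s)
      am <- make_allele_matrix(m, w)
      ph <- solve_wmec(am, p_hifi)
      expect_equal(ph$mec_cost, bf_wmec(m, am$w), tolerance = 1e-6)
    }
  })
})

test_that("wMEC cost is invariant to column allele relabeling and side swap", {
  withr::with_seed(777, {
    for (trial in 1:20) {
      m <- matrix(sample(c(0L, 1L, NA), 24, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), 6, 4)
      if (all(is.na(m))) next
      am <- make_allele_matrix(m)
      c0 <- solve_wmec(am, p_hifi)$mec_cost
      # flip all entries of one column
      m2 <- m
      m2[, 2] <- 1L - m2[, 2]
      expect_equal(solve_wmec(make_allele_matrix(m2), p_hifi)$mec_cost, c0)
    }
  })
})

test_that("planted bipartitions are recovered under 5% entry noise", {
  withr::with_seed(31415, {
    hits <- 0L
    trials <- 200L
    for (t in 1:trials) {
      n <- 10; s <- 6
      truth <- rep(c(0L, 1L), each = n / 2)
      hap <- rbind(sample(c(0L, 1L), s, TRUE))
      m <- matrix(NA_integer_, n, s)
      for (i in 1:n) m[i, ] <- if (truth[i] == 0) hap else 1L - hap
      flip <- which(runif(n * s) < 0.05)
      m[flip] <- 1L - m[flip]
      ph <- solve_wmec(make_allele_matrix(m), p_hifi)
      got <- as.integer(ph$assignment$haplotype == "H2")
      if (all(got == truth) || all(got == 1L - truth)) hits <- hits + 1L
    }
    expect_gte(hits / trials, 0.95)
  })
})

test_that("downsampling caps column coverage and still assigns every row", {
  withr::with_seed(2718, {
    n <- 30; s <- 5
    truth <- rep(c(0L, 1L), each = n / 2)
    hap <- rbind(sample(c(0L, 1L), s, TRUE))
    m <- matrix(NA_integer_, n, s,
                dimnames = list(sprintf("r%02d", 1:n), NULL))
    for (i in 1:n) m[i, ] <- if (truth[i] == 0) hap else 1L - hap
    p_low <- assembly_params("hifi", max_phasing_coverage = 8)
    ph <- solve_wmec(make_allele_matrix(m), p_low)
    expect_equal(nrow(ph$assignment), n)   # every matrix row assigned
    got <- as.integer(ph$assignment$haplotype == "H2")
    expect_true(all(got == truth) || all(got == 1L - truth))
  })
})

test_that("unphasable reads are assigned to both groups", {
  ph <- structure(list(
    assignment = tibble::tibble(read_id = c("a", "b"),
                                haplotype = c("H1", "H2")),
    mec_cost = 0, n_sites = 3L), class = "hb_phasing")
  lab <- assign_unphased(c("a", "b", "c"), ph)
  expect_equal(lab$label[lab$read_id == "c"], "both")
  expect_equal(lab$label[lab$read_id == "a"], "H1")
  # zero sites: everything 'both'
  ph0 <- structure(list(assignment = tibble::tibble(read_id = character(),
                                                    haplotype = character()),
                        mec_cost = 0, n_sites = 0L), class = "hb_phasing")
  lab0 <- assign_unphased(c("a", "b"), ph0)
  expect_true(all(lab0$label == "both"))
  # bookkeeping: |H1| + |H2| + |both| equals the cluster size
  expect_equal(nrow(lab), 3L)
})
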