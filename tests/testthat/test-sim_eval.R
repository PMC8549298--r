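test_that("a zero-rate diploid is homozygous and simulation is seed-exact", {
  tr <- simulate_diploid(5000, snp_rate = 0, indel_rate = 0, seed = 3)
  expect_equal(tr$hap1, tr$hap2)
  expect_equal(nrow(tr$het_sites), 0L)
  expect_equal(nrow(tr$indels), 0L)

  tr2 <- simulate_diploid(5000, snp_rate = 0.01, indel_rate = 0.001, seed = 9)
  tr3 <- simulate_diploid(5000, snp_rate = 0.01, indel_rate = 0.001, seed = 9)
  expect_identical(tr2, tr3)
  tr4 <- simulate_diploid(5000, snp_rate = 0.01, indel_rate = 0.001, seed = 10)
  expect_false(tr2$hap1 == tr4$hap1)
})

test_that("het-site counts follow the binomial expectation", {
  tr <- simulate_diploid(100000, snp_rate = 0.01, seed = 11)
  n <- nrow(tr$het_sites)
  mu <- 100000 * 0.01
  sd3 <- 3 * sqrt(100000 * 0.01 * 0.99)
  expect_gt(n, mu - sd3)
  expect_lt(n, mu + sd3)
  # recorded alleles actually differ and match the sequences
  expect_true(all(tr$het_sites$hap1_allele != tr$het_sites$hap2_allele))
  idx <- tr$het_sites$position + 1L
  expect_equal(substring(tr$hap1, idx, idx), tr$het_sites$hap1_allele)
  expect_equal(substring(tr$hap2, idx, idx), tr$het_sites$hap2_allele)
})

test_that("error-free reads are exact substrings with faithful truth records", {
  tr <- simulate_diploid(20000, snp_rate = 0.01, seed = 21)
  sim <- simulate_reads(tr, coverage_per_hap = 3, mean_len = 3000,
                        len_sd = 500, seed = 22)
  expect_gt(nrow(sim$reads), 0)
  for (i in seq_len(nrow(sim$reads))) {
    rt <- sim$read_truth[i, ]
    hs <- if (rt$hap == 1) tr$hap1 else tr$hap2
    frag <- substr(hs, rt$start + 1, rt$end)
    if (rt$strand == "-") frag <- rc_oracle(frag)
    expect_equal(sim$reads$sequence[i], frag)
  }
})

test_that("simulated bases hit the coverage target", {
  tr <- simulate_diploid(100000, snp_rate = 0.01, seed = 31)
  sim <- simulate_reads(tr, coverage_per_hap = 20, mean_len = 10000,
                        len_sd = 2000, seed = 32)
  total <- sum(sim$reads$length)
  expect_gt(total, 0.95 * 4e6)
  expect_lt(total, 1.05 * 4e6 + 60000)  # one read of slack per haplotype
})

test_that("the empirical substitution rate matches the nominal rate", {
  tr <- simulate_diploid(60000, snp_rate = 0, seed = 41)
  sim <- simulate_reads(tr, coverage_per_hap = 10, mean_len = 6000,
                        len_sd = 1000, err_sub = 0.10, seed = 42)
  expect_gt(sum(sim$reads$length), 1e6)
  mism <- 0; tot <- 0
  for (i in seq_len(nrow(sim$reads))) {
    rt <- sim$read_truth[i, ]
    hs <- if (rt$hap == 1) tr$hap1 else tr$hap2
    frag <- substr(hs, rt$start + 1, rt$end)
    if (rt$strand == "-") frag <- rc_oracle(frag)
    a <- strsplit(frag, "")[[1]]
    b <- strsplit(sim$reads$sequence[i], "")[[1]]
    mism <- mism + sum(a != b)
    tot <- tot + length(a)
  }
  expect_lt(abs(mism / tot - 0.10), 0.005)
})

test_that("N50 satisfies its defining property against the oracle", {
  withr::with_seed(51, {
    for (trial in 1:50) {
      lens <- sample.int(100000, sample(1:40, 1), replace = TRUE)
      expect_equal(n50_value(lens), n50_oracle(lens))
      g <- sum(lens) * runif(1, 0.5, 2)
      expect_equal(n50_value(lens, total = g), n50_oracle(lens, total = g))
    }
  })
  expect_true(is.na(n50_value(integer(0))))
  expect_true(is.na(n50_value(c(10L, 20L), total = 1e6)))
})

test_that("evaluating the truth haplotypes is the fixed point", {
  tr <- simulate_diploid(30000, snp_rate = 0.01, seed = 61)
  contigs <- tibble::tibble(id = c("h1", "h2"),
                            sequence = c(tr$hap1, tr$hap2))
  ev <- evaluate_assembly(contigs, tr)
  expect_equal(ev$haplotype_coverage, 100, tolerance = 0.001)
  expect_equal(ev$switch_error_rate, 0)
  expect_equal(ev$duplication_ratio, 1, tolerance = 0.001)
  expect_equal(ev$qv_identity, 60)
  d <- tidy(ev)
  expect_setequal(d$best_hap, 1:2)
})

test_that("half of one haplotype covers a quarter of the diploid total", {
  tr <- simulate_diploid(40000, snp_rate = 0.01, seed = 62)
  half <- tibble::tibble(id = "c", sequence = substr(tr$hap1, 1, 20000))
  ev <- evaluate_assembly(half, tr)
  expect_equal(ev$haplotype_coverage, 25, tolerance = 0.5)
})

test_that("switch errors count adjacent het-site pairs that change phase", {
  tr <- simulate_diploid(30000, snp_rate = 0.002, seed = 63)
  het <- tr$het_sites
  expect_gte(nrow(het), 11)
  # chimeric contig: hap1 alleles at 6 sites, then hap2 alleles from site 7 on
  cut_site <- het$position[6]
  cut <- cut_site + 500  # between site 6 and site 7
  expect_lt(cut, het$position[7])
  chim <- paste0(substr(tr$hap1, 1, cut),
                 substr(tr$hap2, cut + 1, nchar(tr$hap2)))
  # restrict to the first 11 sites by truncating after site 11
  endp <- het$position[11] + 200
  chim <- substr(chim, 1, endp)
  ev <- evaluate_assembly(tibble::tibble(id = "chim", sequence = chim), tr)
  d <- tidy(ev)
  expect_equal(d$n_sites, 11L)
  expect_equal(d$n_switches, 1L)
  expect_equal(ev$switch_error_rate, 100 * 1 / 10, tolerance = 1e-6)
})

test_that("an empty contig set reports zero coverage and NA rates", {
  tr <- simulate_diploid(10000, snp_rate = 0.01, seed = 64)
  ev <- evaluate_assembly(tibble::tibble(id = character(),
                                         sequence = character()), tr)
  expect_equal(ev$haplotype_coverage, 0)
  expect_true(is.na(ev$switch_error_rate))
  expect_true(is.na(ev$duplication_ratio))
})
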