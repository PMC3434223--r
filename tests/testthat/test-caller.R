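test_that("editing fraction matches published derived columns", {
  expect_equal(round(100 * editing_fraction(c(0, 79, 0, 117), "T", "C"), 2),
               40.31)
  expect_equal(editing_fraction(c(0, 0, 15, 0), "A", "G"), 1.0)
  expect_equal(editing_fraction(c(10, 0, 0, 0), "A", "G"), 0.0)
  expect_equal(editing_fraction(c(0, 0, 0, 0), "A", "G"), 0.0)
  expect_error(editing_fraction(c(1, 1, 1, 1), "A", "A"))
})

test_that("Fisher exact test matches enumeration and stats::fisher.test", {
  expect_equal(fisher_site_test(1, 1, 1, 1), 1.0)
  expect_equal(fisher_site_test(10, 0, 1000, 0), 1.0)
  # strongly edited site against a large background
  p <- fisher_site_test(96, 167, 100000, 30)
  expect_equal(p, enum_fisher(96, 167, 100000, 30), tolerance = 1e-12)
  expect_lt(p, 1e-50)
  expect_error(fisher_site_test(0, 0, 5, 5), "site row")
  expect_error(fisher_site_test(0, 0, 0, 0))
})

test_that("Fisher p equals brute-force enumeration on random small tables", {
  set.seed(7)
  for (i in 1:200) {
    n <- sample(1:200, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    if (a + b == 0) a <- 1
    p <- fisher_site_test(a, b, c, d)
    expect_equal(p, enum_fisher(a, b, c, d), tolerance = 1e-10)
    expect_equal(p, stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                 tolerance = 1e-8)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("one-sided enrichment tail is monotone in the alt count", {
  # at fixed margins, moving reads from ref to alt at the site can only
  # strengthen the enrichment tail
  one_sided <- function(a, b, c, d)
    stats::phyper(b - 1, b + d, a + c, a + b, lower.tail = FALSE)
  prev <- Inf
  for (alt in seq(0, 30, by = 5)) {
    p1 <- one_sided(30 - alt, alt, 10000, 10)
    expect_lte(p1, prev + 1e-12)
    prev <- p1
  }
})

test_that("BH adjustment equals the naive step-up and p.adjust", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(11)
  for (i in 1:25) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, naive_bh(p))
    expect_equal(q, stats::p.adjust(p, "BH"))
    expect_true(all(q >= p))
    o <- order(p)
    expect_false(is.unsorted(q[o]))
  }
})

test_that("caller recovers a planted 40% site and drops a 5% site", {
  ref <- make_reference(51, n_genes = 4L)
  t40 <- plant_sites(ref, n_editing = 1L, levels = 0.4, n_het_snps = 0L,
                     n_hom_snps = 0L, seed = 52)
  reads <- simulate_reads(t40, mean_coverage = 100, seed = 53)
  sites <- pileup(reads$sam, t40$genome)
  spec <- build_spectrum(sites, snp_table())
  cand <- call_candidates(sites, spec, snp_table(), t40$models,
                          caller_config(), genome = t40$genome)
  hit <- cand[cand$pos == t40$editing$pos[1], ]
  expect_equal(nrow(hit), 1L)
  expect_lt(abs(hit$editing_fraction - 0.40), 0.10)

  # a site whose filtered A/G composition sits below the 10% editing
  # threshold is never reported, however significant the test would be
  low <- sites[sites$pos == t40$editing$pos[1], ]
  tot <- low$A + low$G
  low$G <- as.integer(floor(0.09 * tot)); low$A <- tot - low$G
  low$raw_G <- low$G; low$raw_A <- low$A
  sites_low <- sites
  sites_low[sites_low$pos == t40$editing$pos[1], ] <- low
  attr(sites_low, "min_quality") <- attr(sites, "min_quality")
  spec_low <- build_spectrum(sites_low, snp_table())
  cand_low <- call_candidates(sites_low, spec_low, snp_table(), t40$models,
                              caller_config(), genome = t40$genome)
  expect_false(t40$editing$pos[1] %in% cand_low$pos)
  # but the same composition passes when the threshold is lowered
  cand_low2 <- call_candidates(sites_low, spec_low, snp_table(), t40$models,
                               caller_config(min_editing_fraction = 0.05),
                               genome = t40$genome)
  expect_true(t40$editing$pos[1] %in% cand_low2$pos)
})

test_that("SNP-table positions are never called and empty input is empty", {
  truth <- small_truth(61, n_editing = 3L, levels = 0.5, n_het = 2L,
                       n_hom = 2L)
  reads <- simulate_reads(truth, mean_coverage = 60, seed = 61)
  sites <- pileup(reads$sam, truth$genome)
  snps <- snp_table(truth$snps$chrom, truth$snps$pos)
  spec <- build_spectrum(sites, snps)
  cand <- call_candidates(sites, spec, snps, truth$models, caller_config(),
                          genome = truth$genome)
  expect_false(any(cand$pos %in% truth$snps$pos))
  empty <- sites[0, ]; attr(empty, "min_quality") <- 25
  expect_equal(nrow(call_candidates(empty, spec, snps, truth$models,
                                    caller_config())), 0L)
})

test_that("every reported candidate satisfies the filter postconditions", {
  truth <- small_truth(71, n_editing = 5L, levels = c(0.2, 0.4, 0.8))
  reads <- simulate_reads(truth, mean_coverage = 60, seed = 71)
  sites <- pileup(reads$sam, truth$genome)
  snps <- snp_table(truth$snps$chrom, truth$snps$pos)
  spec <- build_spectrum(sites, snps)
  cfg <- caller_config()
  cand <- call_candidates(sites, spec, snps, truth$models, cfg,
                          genome = truth$genome)
  expect_gt(nrow(cand), 0L)
  for (i in seq_len(nrow(cand))) {
    cd <- cand[i, ]
    expect_false(snp_contains(snps, cd$chrom, cd$pos))            # (i)
    expect_true(cd$ref == ifelse(cd$strand == "+", "A", "T"))     # (ii)
    others <- setdiff(c("A", "C", "G", "T"), c(cd$ref, cd$alt))
    expect_equal(cd[[others[1]]] + cd[[others[2]]], 0L)           # (iii)
    expect_gte(cd$coverage, cfg$min_coverage)                     # (iv)
    expect_gte(cd$editing_fraction, cfg$min_editing_fraction)     # (v)
    expect_lte(cd$fdr, cfg$fdr_threshold)                         # (vi)
    expect_gte(cd$fdr, cd$p_value)
    expect_identical(cd$region, "CDS")                            # (vii)
    expect_equal(cd$editing_fraction,
                 editing_fraction(c(cd$A, cd$C, cd$G, cd$T), cd$ref, cd$alt))
  }
  expect_false(is.unsorted(cand$p_value))
})

test_that("quality-threshold mismatches between inputs are contract errors", {
  truth <- small_truth(81)
  reads <- simulate_reads(truth, mean_coverage = 20, seed = 81)
  sites <- pileup(reads$sam, truth$genome, min_quality = 25)
  spec <- build_spectrum(sites, snp_table())
  cfg30 <- caller_config(min_base_quality = 30)
  expect_error(call_candidates(sites, spec, snp_table(), truth$models, cfg30),
               "Q25")
  sites30 <- pileup(reads$sam, truth$genome, min_quality = 30)
  expect_error(call_candidates(sites30, spec, snp_table(), truth$models,
                               cfg30), "spectrum")
})

test_that("the rounded-expected-counts background remains available", {
  truth <- small_truth(91, n_editing = 2L, levels = 0.5)
  reads <- simulate_reads(truth, mean_coverage = 80, seed = 91)
  sites <- pileup(reads$sam, truth$genome)
  snps <- snp_table(truth$snps$chrom, truth$snps$pos)
  spec <- build_spectrum(sites, snps)
  cand <- call_candidates(sites, spec, snps, truth$models,
                          caller_config(background = "expected"),
                          genome = truth$genome)
  expect_true(all(truth$editing$pos %in% cand$pos))
})
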