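test_that("single-site tally separates raw and quality-filtered counts", {
  sc <- pileup_site_counts(obs_df(c("A", "G", "G"), c(30, 20, 30)), "A",
                           min_quality = 25)
  expect_equal(unlist(sc[c("A", "C", "G", "T")], use.names = FALSE),
               c(1L, 0L, 1L, 0L))
  expect_equal(unlist(sc[paste0("raw_", c("A", "C", "G", "T"))],
                      use.names = FALSE), c(1L, 0L, 2L, 0L))
  # no observations
  sc0 <- pileup_site_counts(obs_df(character(0), integer(0)), "A")
  expect_equal(sc0$coverage, 0L)
  # all below threshold: filtered zero, raw kept
  sc2 <- pileup_site_counts(obs_df(c("C", "C"), 10), "A", min_quality = 25)
  expect_equal(sc2$coverage, 0L)
  expect_equal(sc2$raw_C, 2L)
  # N and duplicate bases count in neither
  sc3 <- pileup_site_counts(obs_df(c("A", "N", "A"), 30,
                                   duplicate = c(FALSE, FALSE, TRUE)), "A")
  expect_equal(sc3$raw_A, 1L)
  expect_equal(sc3$A, 1L)
})

.toy_sites <- function() {
  # 100 ref-A matching bases across two sites, one A>G and one C>T mismatch
  s <- data.frame(
    chrom = "chr1", pos = c(10L, 20L, 30L), ref = c("A", "A", "C"),
    raw_A = c(60L, 40L, 0L), raw_C = c(0L, 0L, 12L), raw_G = c(0L, 1L, 0L),
    raw_T = c(0L, 0L, 1L),
    A = c(60L, 40L, 0L), C = c(0L, 0L, 12L), G = c(0L, 1L, 0L),
    T = c(0L, 0L, 1L), coverage = c(60L, 41L, 13L),
    n_plus = c(60L, 41L, 13L), n_minus = 0L, stringsAsFactors = FALSE)
  attr(s, "min_quality") <- 25
  s
}

test_that("spectrum accumulates matches and mismatches, masking SNPs", {
  spec <- build_spectrum(.toy_sites(), snp_table())
  expect_equal(spec$sub_counts[["A>G"]], 1)
  expect_equal(spec$sub_counts[["C>T"]], 1)
  expect_equal(sum(spec$sub_counts), 2)
  expect_equal(spec$match_counts[["A"]], 100)
  expect_equal(spec$match_counts[["C"]], 12)
  # masking the A>G site removes its whole contribution
  spec2 <- build_spectrum(.toy_sites(), snp_table("chr1", 20L))
  expect_equal(spec2$sub_counts[["A>G"]], 0)
  expect_equal(spec2$sub_counts[["C>T"]], 1)
  expect_equal(spec2$match_counts[["A"]], 60)
  expect_equal(spec2$masked_sites, 1L)
  # empty stream
  spec3 <- build_spectrum(.empty <- {
    e <- .toy_sites()[0, ]; attr(e, "min_quality") <- 25; e
  }, snp_table())
  expect_true(all(spec3$sub_counts == 0))
  # missing threshold provenance is a contract error
  bad <- .toy_sites(); attr(bad, "min_quality") <- NULL
  expect_error(build_spectrum(bad), "min_quality")
  # restriction to annotated territory drops sites outside the exons
  m <- gene_model("t", "g", "chr1", "+", 15L, 25L)  # covers only pos 20
  spec4 <- build_spectrum(.toy_sites(), snp_table(), restrict_to = list(m))
  expect_equal(spec4$match_counts[["A"]], 40)
  expect_equal(spec4$sub_counts[["C>T"]], 0)
  expect_equal(spec4$sub_counts[["A>G"]], 1)
})

test_that("spectrum frequencies normalize as defined", {
  spec <- build_spectrum(.toy_sites(), snp_table())
  fr <- spectrum_frequencies(spec)
  expect_equal(fr$type_freq[["A>G"]], 0.5)
  expect_equal(sum(fr$type_freq), 1)
  expect_equal(fr$per_ref_rate[["A>G"]], 1 / 101)
  # all-zero spectrum -> all zero; sum of type_freq in {0, 1} exactly
  e <- .toy_sites()[0, ]; attr(e, "min_quality") <- 25
  zero <- build_spectrum(e, snp_table())
  expect_identical(sum(spectrum_frequencies(zero)$type_freq), 0)
  # single nonzero type normalizes to 1
  one <- zero; one$sub_counts[["T>C"]] <- 7
  expect_equal(spectrum_frequencies(one)$type_freq[["T>C"]], 1)
})

test_that("raising the quality threshold never increases filtered counts", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    obs <- obs_df(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE),
                  sample(0:40, n, replace = TRUE))
    prev <- NULL
    for (q in c(0, 10, 25, 30, 41)) {
      sc <- pileup_site_counts(obs, "A", min_quality = q)
      cnt <- unlist(sc[c("A", "C", "G", "T")], use.names = FALSE)
      if (!is.null(prev)) expect_true(all(cnt <= prev))
      expect_true(all(cnt <= unlist(sc[paste0("raw_", c("A", "C", "G", "T"))],
                                    use.names = FALSE)))
      prev <- cnt
    }
  }
})

test_that("pileup recovers the planted Q30 error rate within 3 binomial SD", {
  ref <- make_reference(31, n_genes = 4L)
  truth <- plant_sites(ref, n_editing = 0L, n_het_snps = 0L, n_hom_snps = 0L,
                       seed = 31)
  reads <- simulate_reads(truth, mean_coverage = 40, seed = 31)
  sites <- pileup(reads$sam, truth$genome, min_quality = 0)
  spec <- build_spectrum(sites, snp_table())
  n_sub <- sum(spec$sub_counts)
  n_tot <- n_sub + sum(spec$match_counts)
  p0 <- 1e-3
  expect_lt(abs(n_sub - n_tot * p0), 3 * sqrt(n_tot * p0 * (1 - p0)))
  # per-reference rates individually near the planted rate
  fr <- spectrum_frequencies(spec)$per_ref_rate
  for (r in c("A", "C", "G", "T")) {
    types <- grep(paste0("^", r, ">"), substitution_types(), value = TRUE)
    expect_lt(abs(sum(fr[types]) - p0), 6e-4)
  }
})

test_that("whole-alignment pileup equals per-site tallies at a known site", {
  truth <- small_truth(33)
  reads <- simulate_reads(truth, mean_coverage = 30, seed = 33)
  sites <- pileup(reads$sam, truth$genome, min_quality = 25)
  e <- truth$editing[1, ]
  row <- sites[sites$chrom == e$chrom & sites$pos == e$pos, ]
  obs <- site_observations(reads$sam, e$chrom, e$pos)
  direct <- pileup_site_counts(obs, e$ref, min_quality = 25)
  expect_equal(unlist(row[c("A", "C", "G", "T")], use.names = FALSE),
               unlist(direct[c("A", "C", "G", "T")], use.names = FALSE))
  expect_equal(row$coverage, direct$coverage)
  expect_identical(row$ref, e$ref)
})

test_that("spectrum TSV serialization round-trips", {
  spec <- build_spectrum(.toy_sites(), snp_table("chr1", 999L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum(spec, f)
  expect_match(readLines(f)[1], "min_quality=25")
  back <- read_spectrum(f)
  expect_equal(back$sub_counts, spec$sub_counts)
  expect_equal(back$match_counts, spec$match_counts)
  expect_equal(back$min_quality, spec$min_quality)
})
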