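test_that("reference construction is deterministic and structurally sound", {
  a <- make_reference(3)
  b <- make_reference(3)
  expect_identical(a$genome, b$genome)
  expect_equal(length(a$models), 4L)
  strands <- vapply(a$models, `[[`, character(1), "strand")
  expect_equal(sum(strands == "+"), 2L)    # alternating strands
  spans <- vapply(a$models, function(m) max(m$exon_end) - min(m$exon_start) + 1L,
                  integer(1))
  # span = sum of exons + sum of introns
  expect_true(all(spans == 3L * 300L + 2L * 200L))
  for (m in a$models) {
    expect_equal(cds_spliced_length(m) %% 3L, 0L)
    expect_gt(cds_spliced_length(m), 0L)
  }
  # genes do not overlap
  iv <- t(vapply(a$models, function(m) c(min(m$exon_start), max(m$exon_end)),
                 integer(2)))
  iv <- iv[order(iv[, 1]), ]
  expect_true(all(iv[-1, 1] > iv[-nrow(iv), 2]))
  expect_error(make_reference(1, exon_len = 10L, exons_per_gene = 1L,
                              utr_len = 10L), "too short")
})

test_that("planted sites sit on transcribed-strand adenosines, disjoint from SNPs", {
  ref <- make_reference(5)
  truth <- plant_sites(ref, n_editing = 6L, levels = c(0.1, 0.4), seed = 5,
                       n_het_snps = 3L, n_hom_snps = 3L)
  expect_equal(nrow(truth$editing), 6L)
  expect_equal(truth$editing$level, rep(c(0.1, 0.4), 3))
  for (i in seq_len(nrow(truth$editing))) {
    e <- truth$editing[i, ]
    expect_identical(genome_base(truth$genome, e$chrom, e$pos),
                     ifelse(e$strand == "+", "A", "T"))
    m <- truth$models[[match(e$transcript_id,
                             vapply(truth$models, `[[`, character(1),
                                    "transcript_id"))]]
    expect_true(e$pos >= m$cds_start && e$pos <= m$cds_end)
  }
  expect_length(intersect(paste(truth$editing$chrom, truth$editing$pos),
                          paste(truth$snps$chrom, truth$snps$pos)), 0L)
  expect_error(plant_sites(ref, n_editing = 10000L, seed = 5), "eligible")
})

test_that("read simulation is deterministic and respects strandedness", {
  truth <- small_truth(9)
  r1 <- simulate_reads(truth, mean_coverage = 15, seed = 9)
  r2 <- simulate_reads(truth, mean_coverage = 15, seed = 9)
  expect_identical(r1$sam, r2$sam)
  expect_identical(r1$tx, r2$tx)
  # stranded mode: mate-1 orientation equals the gene strand
  strands <- stats::setNames(vapply(truth$models, `[[`, character(1),
                                    "strand"),
                             vapply(truth$models, `[[`, character(1),
                                    "transcript_id"))
  tx_of <- sub("_f[0-9]+$", "", r1$sam$qname)
  m1 <- r1$sam[r1$sam$mate1 & !r1$sam$mate2, ]
  expect_true(all(m1$strand == strands[sub("_f[0-9]+$", "", m1$qname)]))
  # unstranded mode uses both orientations
  r3 <- simulate_reads(truth, mean_coverage = 15, stranded = FALSE, seed = 9)
  m1u <- r3$sam[r3$sam$mate1 & !r3$sam$mate2, ]
  ori <- m1u$strand == strands[sub("_f[0-9]+$", "", m1u$qname)]
  expect_true(any(ori) && any(!ori))
})

test_that("planted allele fractions match binomial expectation in RNA", {
  ref <- make_reference(15)
  truth <- plant_sites(ref, n_editing = 3L, levels = 0.4, n_het_snps = 0L,
                       n_hom_snps = 0L, seed = 15)
  reads <- simulate_reads(truth, mean_coverage = 200, seed = 15)
  sites <- pileup(reads$sam, truth$genome, min_quality = 0)
  for (i in seq_len(nrow(truth$editing))) {
    e <- truth$editing[i, ]
    row <- sites[sites$chrom == e$chrom & sites$pos == e$pos, ]
    alt <- if (e$strand == "+") row$G else row$C
    refb <- if (e$strand == "+") row$A else row$T
    n <- alt + refb
    expect_gt(n, 50)
    expect_lt(abs(alt / n - 0.4), 3 * sqrt(0.4 * 0.6 / n))
  }
})

test_that("DNA reads carry SNPs but never editing", {
  ref <- make_reference(17)
  truth <- plant_sites(ref, n_editing = 2L, levels = 0.9, n_het_snps = 1L,
                       n_hom_snps = 1L, seed = 17)
  d1 <- simulate_dna_reads(truth, mean_coverage = 100, seed = 18)
  expect_identical(d1, simulate_dna_reads(truth, mean_coverage = 100,
                                          seed = 18))
  sites <- pileup(d1, truth$genome, min_quality = 0)
  for (i in 1:2) {
    e <- truth$editing[i, ]
    row <- sites[sites$chrom == e$chrom & sites$pos == e$pos, ]
    alt <- if (e$strand == "+") row$G else row$C
    # alt observations consistent with the error rate alone (eps/3 per base)
    expect_lte(alt, stats::qbinom(0.999, row$coverage, 10^(-3.5) / 3) + 1)
  }
  het <- truth$snps[truth$snps$genotype == "het", ][1, ]
  row <- sites[sites$chrom == het$chrom & sites$pos == het$pos, ]
  frac <- row[[het$alt]] / row$coverage
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / row$coverage))
  hom <- truth$snps[truth$snps$genotype == "hom", ][1, ]
  row2 <- sites[sites$chrom == hom$chrom & sites$pos == hom$pos, ]
  expect_gt(row2[[hom$alt]] / row2$coverage, 0.95)
})

test_that("emitted alignments re-parse through the SAM layer with no loss", {
  truth <- small_truth(19)
  reads <- simulate_reads(truth, mean_coverage = 8, seed = 19)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads$sam, f, genome = truth$genome)
  back <- read_sam(f)
  expect_equal(nrow(back), nrow(reads$sam))
  # pileups from the original and re-parsed alignments are identical
  s1 <- pileup(reads$sam, truth$genome)
  s2 <- pileup(back, truth$genome)
  expect_identical(s1, s2)
  # truth tables serialize
  dir <- withr::local_tempdir()
  paths <- write_truth(truth, dir)
  expect_true(all(file.exists(paths)))
  tt <- utils::read.delim(paths[1])
  expect_equal(nrow(tt), nrow(truth$editing))
})

test_that("FASTQ export emits reads in sequencing orientation", {
  truth <- small_truth(25)
  reads <- simulate_reads(truth, mean_coverage = 5, seed = 25)
  f <- withr::local_tempfile(fileext = ".fq")
  write_fastq(reads$sam, f)
  lines <- readLines(f)
  expect_equal(length(lines), 4L * nrow(reads$sam))
  i <- which(reads$sam$strand == "-")[1]
  block <- lines[(4 * (i - 1) + 1):(4 * i)]
  expect_identical(block[2], revcomp(reads$sam$seq[i]))
})
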