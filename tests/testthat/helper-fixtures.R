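# shared fixtures, all built in code

# the two-exon model used throughout: exons 101-200 and 301-400
two_exon_model <- function(strand = "+", cds = FALSE, chrom = "chr1") {
  gene_model("tx1", "G1", chrom, strand,
             exon_start = c(101L, 301L), exon_end = c(200L, 400L),
             cds_start = if (cds) 131L else NA_integer_,
             cds_end = if (cds) 370L else NA_integer_)
}

# genome whose exonic bases spell `txseq` for `model` (strand-aware);
# everything else is filled with `bg`
genome_for_tx <- function(model, txseq, bg = "C", pad = 50L) {
  glen <- max(model$exon_end) + pad
  g <- rep(bg, glen)
  gpos <- genome_positions(model)
  stopifnot(nchar(txseq) == length(gpos))
  # exonic bases in genome orientation
  tx_g <- strsplit(if (model$strand == "+") txseq else revcomp(txseq),
                   "")[[1]]
  g[sort(gpos)] <- tx_g
  stats::setNames(paste(g, collapse = ""), model$chrom)
}

# a base-observation data.frame
obs_df <- function(bases, phred, duplicate = FALSE, strand = "+") {
  data.frame(read_id = sprintf("r%d", seq_along(bases)), base = bases,
             phred = rep_len(phred, length(bases)),
             strand = rep_len(strand, length(bases)),
             duplicate = rep_len(duplicate, length(bases)),
             stringsAsFactors = FALSE)
}

# a minimal unpaired SAM record stack: `n` reads of `base` at one position
stack_sam <- function(chrom, pos, base, n, phred = 35, dup = rep(FALSE, n)) {
  if (n == 0L) return(empty_sam())
  decode_sam_flags(data.frame(
    qname = sprintf("s%03d", seq_len(n)),
    flag = ifelse(dup, 1024L, 0L), rname = chrom, pos = pos, mapq = 60L,
    cigar = "1M", rnext = "*", pnext = 0L, tlen = 0L, seq = base,
    qual = intToUtf8(phred + 33L), nh = 1L, stringsAsFactors = FALSE))
}

# independent per-base transcript->genome coordinate oracle: walk the exons
# base by base (plus strand), reverse the walk for minus strand
naive_tx_map <- function(model) {
  g <- integer(0)
  for (i in seq_along(model$exon_start))
    for (p in model$exon_start[i]:model$exon_end[i]) g <- c(g, p)
  if (model$strand == "-") g <- rev(g)
  g
}

# brute-force two-sided Fisher p via log-factorial table probabilities,
# independent of dhyper
enum_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; n <- r1 + r2
  logp <- function(x) {
    # P(table with top-left = x) under fixed margins
    lgamma(r1 + 1) + lgamma(r2 + 1) + lgamma(c1 + 1) + lgamma(c2 + 1) -
      lgamma(n + 1) - lgamma(x + 1) - lgamma(r1 - x + 1) -
      lgamma(c1 - x + 1) - lgamma(c2 - r1 + x + 1)
  }
  support <- max(0, r1 - c2):min(r1, c1)
  lp <- vapply(support, logp, numeric(1))
  lobs <- logp(a)
  sum(exp(lp[lp <= lobs + 1e-7]))
}

# naive O(m^2) Benjamini-Hochberg step-up
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

# log10 grid-search oracle for the editing LLR
grid_llr <- function(obs, ref_base, alt_base, step = 1e-5) {
  is_alt <- obs$base == alt_base
  eps <- 10^(-obs$phred / 10)
  p_alt <- ifelse(is_alt, 1 - eps, eps / 3)
  p_ref <- ifelse(is_alt, eps / 3, 1 - eps)
  f <- seq(0, 1, by = step)
  ll <- vapply(f, function(x) sum(log10(x * p_alt + (1 - x) * p_ref)),
               numeric(1))
  best <- which.max(ll)
  list(llr = max(ll[best] - ll[1], 0), f_hat = f[best])
}

# simulated base observations at one site: molecules edited at level f,
# bases then miscalled at the Phred error rate
sim_site_obs <- function(n, f, phred = 30, seed = 1) {
  set.seed(seed)
  eps <- 10^(-phred / 10)
  edited <- runif(n) < f
  true_base <- ifelse(edited, "G", "A")
  err <- runif(n) < eps
  base <- true_base
  base[err] <- vapply(true_base[err], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  obs_df(base, phred)
}

# small end-to-end world
small_truth <- function(seed, n_editing = 4L, levels = 0.3,
                        n_het = 1L, n_hom = 1L) {
  ref <- make_reference(seed, n_genes = 4L, exons_per_gene = 3L,
                        exon_len = 250L, intron_len = 150L)
  plant_sites(ref, n_editing = n_editing, levels = levels,
              n_het_snps = n_het, n_hom_snps = n_hom, seed = seed + 1L)
}
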