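.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Build a synthetic reference genome with spliced gene models
#'
#' One chromosome of random sequence carrying `n_genes` non-overlapping
#' multi-exon genes, alternating between the plus and minus strand. Each
#' transcript has a 5' UTR, a CDS whose spliced length is divisible by 3, and
#' a 3' UTR. Deterministic for a given seed.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Number of genes (default 4, two per strand).
#' @param exons_per_gene Exons per gene (default 3).
#' @param exon_len Exon length in bp (default 300).
#' @param intron_len Intron length in bp (default 200).
#' @param utr_len 5' and 3' UTR length in transcript bases (default 60).
#' @param intergenic Gap between genes (default 500).
#' @param chrom Chromosome name (default "chr1").
#' @return List of class `sim_reference` with `genome` (named character) and
#'   `models` (list of [gene_model()]).
#' @export
make_reference <- function(seed, n_genes = 4L, exons_per_gene = 3L,
                           exon_len = 300L, intron_len = 200L, utr_len = 60L,
                           intergenic = 500L, chrom = "chr1") {
  stopifnot(n_genes >= 1, exons_per_gene >= 1, exon_len >= 1,
            intron_len >= 0, utr_len >= 0, intergenic >= 1)
  txlen <- exons_per_gene * exon_len
  if (txlen - 2L * utr_len < 3L)
    stop("make_reference: exons too short to fit UTRs and a CDS")
  .with_seed(seed, {
    span <- exons_per_gene * exon_len + (exons_per_gene - 1L) * intron_len
    glen <- n_genes * span + (n_genes + 1L) * intergenic
    genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                    collapse = "")
    names(genome) <- NULL
    genome <- stats::setNames(genome, chrom)
    models <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      gstart <- intergenic * g + span * (g - 1L) + 1L
      ex_start <- gstart + (seq_len(exons_per_gene) - 1L) *
        (exon_len + intron_len)
      ex_end <- ex_start + exon_len - 1L
      strand <- if (g %% 2L == 1L) "+" else "-"
      cds_len <- 3L * ((txlen - 2L * utr_len) %/% 3L)
      m <- gene_model(transcript_id = paste0("tx", g),
                      gene_name = paste0("GENE", g),
                      chrom = chrom, strand = strand,
                      exon_start = ex_start, exon_end = ex_end)
      cds_g <- tx_to_genome(m, c(utr_len + 1L, utr_len + cds_len))
      models[[g]] <- gene_model(transcript_id = m$transcript_id,
                                gene_name = m$gene_name, chrom = chrom,
                                strand = strand, exon_start = ex_start,
                                exon_end = ex_end,
                                cds_start = min(cds_g), cds_end = max(cds_g))
    }
    structure(list(genome = genome, models = models, seed = seed),
              class = "sim_reference")
  })
}

#' Plant editing sites and SNPs into a synthetic reference
#'
#' Editing sites are placed only at positions that read as adenosine on the
#' transcribed strand (genomic A in plus-strand genes, genomic T in
#' minus-strand genes); SNPs at other exonic positions. The two sets are
#' disjoint.
#'
#' @param ref A `sim_reference` from [make_reference()].
#' @param n_editing Number of editing sites.
#' @param levels Editing levels in `[0, 1]`, recycled over sites.
#' @param n_het_snps,n_hom_snps Numbers of heterozygous / homozygous-alt
#'   SNPs.
#' @param seed Integer RNG seed.
#' @param region Plant editing within `"cds"` (default, so that candidates
#'   survive the coding-region filter) or anywhere `"exonic"`.
#' @return List of class `sim_truth`: genome, models, `editing` data.frame
#'   (chrom, pos, strand, level, transcript_id, ref, alt), `snps` data.frame
#'   (chrom, pos, genotype, ref, alt), seed.
#' @export
plant_sites <- function(ref, n_editing = 5L, levels = 0.4,
                        n_het_snps = 2L, n_hom_snps = 2L, seed = 1L,
                        region = c("cds", "exonic")) {
  region <- match.arg(region)
  stopifnot(inherits(ref, "sim_reference"))
  .with_seed(seed, {
    pools <- lapply(ref$models, function(m) {
      gpos <- sort(genome_positions(m))
      if (region == "cds")
        gpos <- gpos[gpos >= m$cds_start & gpos <= m$cds_end]
      base <- genome_base(ref$genome, m$chrom, gpos)
      want <- if (m$strand == "+") "A" else "T"
      data.frame(chrom = m$chrom, pos = gpos[base == want],
                 strand = m$strand, transcript_id = m$transcript_id,
                 ref = want, stringsAsFactors = FALSE)
    })
    pool <- do.call(rbind, pools)
    if (nrow(pool) < n_editing)
      stop("plant_sites: only ", nrow(pool),
           " eligible transcribed-strand adenosines for ", n_editing,
           " editing sites")
    idx <- sample.int(nrow(pool), n_editing)
    editing <- pool[idx, , drop = FALSE]
    editing$level <- rep_len(levels, n_editing)
    editing$alt <- ifelse(editing$strand == "+", "G", "C")
    rownames(editing) <- NULL
    # SNPs: exonic positions disjoint from editing sites
    ex_all <- do.call(rbind, lapply(ref$models, function(m)
      data.frame(chrom = m$chrom, pos = sort(genome_positions(m)),
                 transcript_id = m$transcript_id, stringsAsFactors = FALSE)))
    ex_all <- ex_all[!paste(ex_all$chrom, ex_all$pos) %in%
                       paste(editing$chrom, editing$pos), , drop = FALSE]
    n_snp <- n_het_snps + n_hom_snps
    if (nrow(ex_all) < n_snp)
      stop("plant_sites: not enough exonic positions for SNPs")
    sidx <- sample.int(nrow(ex_all), n_snp)
    snps <- ex_all[sidx, c("chrom", "pos"), drop = FALSE]
    snps$genotype <- rep(c("het", "hom"), c(n_het_snps, n_hom_snps))
    snps$ref <- genome_base(ref$genome, snps$chrom, snps$pos)
    snps$alt <- vapply(snps$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    rownames(snps) <- NULL
    structure(list(genome = ref$genome, models = ref$models,
                   editing = editing, snps = snps, seed = seed),
              class = "sim_truth")
  })
}

# alleles carried by one molecule at the variant tx positions
.molecule_variants <- function(var_tx) {
  if (nrow(var_tx) == 0L) return(integer(0))
  carry <- stats::runif(nrow(var_tx)) < var_tx$prob
  which(carry)
}

#' Simulate RNA-Seq reads with planted editing
#'
#' Fragments are drawn from each transcript; at every planted editing site a
#' covering fragment independently carries the edited base with probability
#' equal to the site's level (before sequencing errors). Heterozygous SNPs
#' are carried with probability 0.5, homozygous-alt SNPs always. Sequencing
#' errors are injected per base at rate `10^(-phred/10)` with a uniform wrong
#' base. Reads are emitted truth-placed as genome-space spliced alignments
#' (bypassing any aligner), together with the matching transcript-space
#' alignments used by the concordance filter.
#'
#' @param truth A `sim_truth` from [plant_sites()].
#' @param mean_coverage Target per-base coverage (default 50).
#' @param read_len Read length (default 50, as in 2x50 bp libraries).
#' @param paired Paired-end (default TRUE).
#' @param stranded Strand-oriented library: read 1 is always sense
#'   (default TRUE).
#' @param phred Constant per-base Phred quality (default 30).
#' @param seed Integer RNG seed.
#' @param fragment_mean,fragment_sd Fragment length distribution
#'   (default 180 +/- 30, clamped to `[read_len, transcript length]`).
#' @return List of class `sim_reads`: `sam` (genome-space alignment
#'   data.frame), `tx` (transcript alignments, see
#'   [transcript_alignment()]).
#' @export
simulate_reads <- function(truth, mean_coverage = 50, read_len = 50L,
                           paired = TRUE, stranded = TRUE, phred = 30L,
                           seed = 1L, fragment_mean = 180, fragment_sd = 30) {
  stopifnot(inherits(truth, "sim_truth"))
  .with_seed(seed, {
    qual_str <- strrep(intToUtf8(phred + 33L), read_len)
    eps <- 10^(-phred / 10)
    sam_rows <- list(); tx_rows <- list()
    for (m in truth$models) {
      txseq <- transcript_seq(m, truth$genome)
      txlen <- nchar(txseq)
      if (read_len > txlen)
        stop("simulate_reads: read length exceeds transcript length")
      # variant positions in transcript coordinates
      ed <- truth$editing[truth$editing$transcript_id == m$transcript_id, ,
                          drop = FALSE]
      sn <- truth$snps[truth$snps$chrom == m$chrom &
                         truth$snps$pos %in% genome_positions(m), ,
                       drop = FALSE]
      var_tx <- data.frame(tx_pos = integer(0), alt = character(0),
                           prob = numeric(0))
      if (nrow(ed) > 0L)
        var_tx <- rbind(var_tx, data.frame(
          tx_pos = genome_to_tx(m, ed$pos), alt = "G", prob = ed$level))
      if (nrow(sn) > 0L)
        var_tx <- rbind(var_tx, data.frame(
          tx_pos = genome_to_tx(m, sn$pos),
          alt = if (m$strand == "+") sn$alt else comp_base(sn$alt),
          prob = ifelse(sn$genotype == "het", 0.5, 1.0)))
      n_read <- if (paired) 2L else 1L
      n_frag <- max(1L, round(mean_coverage * txlen / (read_len * n_read)))
      flen <- pmin(pmax(round(stats::rnorm(n_frag, fragment_mean,
                                           fragment_sd)), read_len), txlen)
      fstart <- 1L + floor(stats::runif(n_frag) * (txlen - flen + 1))
      nr <- n_frag * n_read
      v_id <- character(nr); v_start <- integer(nr)
      v_bases <- character(nr); v_rs <- character(nr)
      k <- 0L
      for (j in seq_len(n_frag)) {
        carry <- .molecule_variants(var_tx)
        qname <- sprintf("%s_f%05d", m$transcript_id, j)
        ends <- if (paired) c(1L, 2L) else 1L
        r1_sense <- stranded || stats::runif(1) < 0.5
        for (mate in ends) {
          if ((mate == 1L) == r1_sense) {
            s <- fstart[j]; rs <- "+"
          } else {
            s <- fstart[j] + flen[j] - read_len; rs <- "-"
          }
          bases <- strsplit(substring(txseq, s, s + read_len - 1L), "")[[1]]
          for (v in carry) {
            tp <- var_tx$tx_pos[v]
            if (tp >= s && tp < s + read_len)
              bases[tp - s + 1L] <- var_tx$alt[v]
          }
          err <- stats::runif(read_len) < eps
          if (any(err))
            bases[err] <- vapply(bases[err], function(b)
              sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
          k <- k + 1L
          v_id[k] <- if (paired) paste0(qname, "/", mate) else qname
          v_start[k] <- s
          v_bases[k] <- paste(bases, collapse = "")
          v_rs[k] <- rs
        }
      }
      tx_rows[[length(tx_rows) + 1L]] <- transcript_alignment(
        v_id, m$transcript_id, v_start, v_bases, qual_str, read_strand = v_rs)
    }
    tx <- do.call(rbind, tx_rows)
    sam <- .tx_to_sam(tx, truth$models, paired = paired)
    structure(list(sam = sam, tx = tx, paired = paired, stranded = stranded,
                   phred = phred, read_len = read_len, seed = seed),
              class = "sim_reads")
  })
}

# convert transcript alignments to genome-space SAM records via projection
.tx_to_sam <- function(tx, models, paired) {
  proj <- project_alignments(tx, models)
  qname <- sub("/[12]$", "", proj$read_id)
  mate2 <- grepl("/2$", proj$read_id)
  flag <- integer(nrow(proj))
  if (paired) {
    flag <- flag + 0x1 + 0x2 + ifelse(mate2, 0x80, 0x40)
    minus <- proj$strand == "-"
    mate_minus <- minus[match(paste0(qname, "/", ifelse(mate2, "1", "2")),
                              proj$read_id)]
    flag <- flag + ifelse(minus, 0x10, 0L) + ifelse(mate_minus, 0x20, 0L)
  } else {
    flag <- flag + ifelse(proj$strand == "-", 0x10, 0L)
  }
  blocks <- lapply(proj$blocks, .parse_blocks)
  cigar <- vapply(blocks, function(b) blocks_to_cigar(b$start, b$end),
                  character(1))
  pos <- vapply(blocks, function(b) b$start[1], integer(1))
  endp <- vapply(blocks, function(b) b$end[nrow(b)], integer(1))
  pnext <- if (paired)
    pos[match(paste0(qname, "/", ifelse(mate2, "1", "2")), proj$read_id)]
  else 0L
  tlen <- if (paired) {
    mend <- endp[match(paste0(qname, "/", ifelse(mate2, "1", "2")),
                       proj$read_id)]
    span <- pmax(endp, mend) - pmin(pos, pnext) + 1L
    ifelse(pos < pnext | (pos == pnext & !mate2), span, -span)
  } else 0L
  df <- data.frame(
    qname = qname, flag = as.integer(flag), rname = proj$chrom, pos = pos,
    mapq = 60L,
    cigar = cigar, rnext = if (paired) "=" else "*",
    pnext = if (paired) pnext else 0L, tlen = tlen,
    seq = proj$bases, qual = proj$quals, nh = 1L, stringsAsFactors = FALSE)
  decode_sam_flags(df)
}

#' Simulate DNA (exome-like) reads
#'
#' Reads drawn uniformly from the genome: SNP alleles are carried per
#' molecule (heterozygous at 50\%, homozygous-alt always); editing is
#' invisible in DNA. Errors as in [simulate_reads()].
#'
#' @param truth A `sim_truth`.
#' @param mean_coverage Target coverage (default 30).
#' @param read_len Read length (default 100).
#' @param phred Constant Phred quality (default 35).
#' @param seed Integer RNG seed.
#' @return Genome-space alignment data.frame (unspliced records).
#' @export
simulate_dna_reads <- function(truth, mean_coverage = 30, read_len = 100L,
                               phred = 35L, seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  .with_seed(seed, {
    qual_str <- strrep(intToUtf8(phred + 33L), read_len)
    eps <- 10^(-phred / 10)
    rows <- list()
    for (chrom in names(truth$genome)) {
      glen <- nchar(truth$genome[[chrom]])
      if (glen < read_len) next
      n <- max(1L, round(mean_coverage * glen / read_len))
      starts <- 1L + floor(stats::runif(n) * (glen - read_len + 1))
      strands <- sample(c("+", "-"), n, replace = TRUE)
      sn <- truth$snps[truth$snps$chrom == chrom, , drop = FALSE]
      for (j in seq_len(n)) {
        s <- starts[j]
        bases <- strsplit(substring(truth$genome[[chrom]], s,
                                    s + read_len - 1L), "")[[1]]
        if (nrow(sn) > 0L) {
          inside <- which(sn$pos >= s & sn$pos < s + read_len)
          for (v in inside) {
            p <- if (sn$genotype[v] == "het") 0.5 else 1.0
            if (stats::runif(1) < p) bases[sn$pos[v] - s + 1L] <- sn$alt[v]
          }
        }
        err <- stats::runif(read_len) < eps
        if (any(err))
          bases[err] <- vapply(bases[err], function(b)
            sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
        rows[[length(rows) + 1L]] <- data.frame(
          qname = sprintf("dna_%s_%06d", chrom, j),
          flag = if (strands[j] == "-") 16L else 0L, rname = chrom,
          pos = s, mapq = 60L, cigar = sprintf("%dM", read_len),
          rnext = "*", pnext = 0L, tlen = 0L,
          seq = paste(bases, collapse = ""), qual = qual_str, nh = 1L,
          stringsAsFactors = FALSE)
      }
    }
    decode_sam_flags(do.call(rbind, rows))
  })
}

#' Add a decoy paralog of one gene to the genome
#'
#' Copies the genomic span of a gene onto a new chromosome with a few random
#' substitutions, mimicking a recently diverged paralog that can attract
#' misaligned reads. No gene model is added for the decoy.
#'
#' @param truth A `sim_truth`.
#' @param transcript_id Gene to duplicate.
#' @param n_mismatch Substitutions introduced into the copy (default 5).
#' @param seed Integer RNG seed.
#' @return The `sim_truth` with the decoy chromosome appended and a `decoy`
#'   field (chrom, src_chrom, src_start, src_end).
#' @export
add_decoy_paralog <- function(truth, transcript_id, n_mismatch = 5L,
                              seed = 1L) {
  m <- NULL
  for (mm in truth$models)
    if (mm$transcript_id == transcript_id) m <- mm
  if (is.null(m)) stop("add_decoy_paralog: unknown transcript ",
                       transcript_id)
  .with_seed(seed, {
    s <- min(m$exon_start); e <- max(m$exon_end)
    seqv <- strsplit(substring(truth$genome[[m$chrom]], s, e), "")[[1]]
    idx <- sample.int(length(seqv), min(n_mismatch, length(seqv)))
    seqv[idx] <- vapply(seqv[idx], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    decoy_chrom <- paste0("decoy_", transcript_id)
    truth$genome <- c(truth$genome,
                      stats::setNames(paste(seqv, collapse = ""),
                                      decoy_chrom))
    truth$decoy <- list(chrom = decoy_chrom, src_chrom = m$chrom,
                        src_start = s, src_end = e)
    truth
  })
}

#' Relocate a fraction of a gene's genome alignments to the decoy paralog
#'
#' Emulates a genome aligner that prefers the paralogous copy for some reads:
#' the affected records keep their CIGAR but move to the decoy chromosome at
#' the homologous offset. The transcriptome-space alignments are unchanged,
#' so [concordance_filter()] removes these reads.
#'
#' @param sam Genome-space alignment data.frame from [simulate_reads()].
#' @param truth A `sim_truth` carrying a `decoy` field.
#' @param transcript_id Gene whose reads may be misplaced.
#' @param fraction Fraction of that gene's fragments to relocate.
#' @param seed Integer RNG seed.
#' @return The modified alignment data.frame.
#' @export
misalign_to_paralog <- function(sam, truth, transcript_id, fraction = 0.5,
                                seed = 1L) {
  if (is.null(truth$decoy)) stop("misalign_to_paralog: no decoy in truth")
  .with_seed(seed, {
    frag <- unique(sam$qname[startsWith(sam$qname,
                                        paste0(transcript_id, "_"))])
    moved <- frag[stats::runif(length(frag)) < fraction]
    sel <- sam$qname %in% moved
    off <- truth$decoy$src_start - 1L
    sam$pos[sel] <- sam$pos[sel] - off
    sam$pnext[sel] <- pmax(sam$pnext[sel] - off, 0L)
    sam$rname[sel] <- truth$decoy$chrom
    sam
  })
}

#' Write reads as FASTQ
#'
#' Emits reads in sequencing (read) orientation: records aligned to the minus
#' strand are reverse-complemented and their qualities reversed.
#'
#' @param aln Alignment data.frame.
#' @param path Output FASTQ file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(aln, path) {
  seqs <- ifelse(aln$strand == "-", revcomp(aln$seq), aln$seq)
  quals <- ifelse(aln$strand == "-",
                  vapply(aln$qual, function(q) intToUtf8(rev(utf8ToInt(q))),
                         character(1), USE.NAMES = FALSE),
                  aln$qual)
  ids <- ifelse(aln$paired, paste0(aln$qname, "/",
                                   ifelse(aln$mate2, "2", "1")), aln$qname)
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  invisible(path)
}

#' Serialize simulation truth tables
#' @param truth A `sim_truth`.
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "editing_truth.tsv")
  p2 <- file.path(dir, "snp_truth.tsv")
  utils::write.table(truth$editing, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$snps, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
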