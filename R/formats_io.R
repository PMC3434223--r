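#' Read a reference genome from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase chromosome sequences
#'   ("genome"), addressable with [genome_base()].
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  g <- toupper(as.character(ss))
  names(g) <- sub("\\s.*$", "", names(g))
  if (any(nchar(g) == 0L)) stop("read_genome: empty sequence in ", path)
  g
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Look up reference bases by chromosome and 1-based position
#' @param genome Genome from [read_genome()].
#' @param chrom Character vector of chromosome names (exact match).
#' @param pos Integer vector of 1-based positions.
#' @return Character vector of single bases.
#' @export
genome_base <- function(genome, chrom, pos) {
  if (!all(chrom %in% names(genome)))
    stop("genome_base: unknown chromosome ",
         paste(setdiff(unique(chrom), names(genome)), collapse = ","))
  unname(substring(genome[chrom], pos, pos))
}

# ---- gene models -----------------------------------------------------------

#' Read gene models from GTF or BED12
#'
#' Coordinates are normalized to 1-based inclusive. For GTF, exons are taken
#' from `exon` features and the CDS from the span of `CDS` features of the
#' same transcript. For BED12, blocks give the exons and the thick interval
#' the CDS (absent when thickStart == thickEnd).
#'
#' @param path Annotation file.
#' @param dialect `"GTF"` or `"BED12"`; default guessed from the extension.
#' @return List of [gene_model()] objects.
#' @export
read_gene_models <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "BED12"
               else if (grepl("\\.gtf$", path, ignore.case = TRUE)) "GTF"
               else stop("read_gene_models: cannot guess dialect for ", path)
  }
  dialect <- toupper(dialect)
  if (!dialect %in% c("GTF", "BED12"))
    stop("read_gene_models: unknown dialect '", dialect, "'")
  if (dialect == "BED12") .read_models_bed12(path) else .read_models_gtf(path)
}

.read_models_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) return(list())
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 12L)
      stop("read_gene_models: malformed BED12 at line ", i, " of ", path)
    chrom <- f[1]
    start0 <- suppressWarnings(as.integer(f[2]))
    thick0 <- suppressWarnings(as.integer(f[7]))
    thick1 <- suppressWarnings(as.integer(f[8]))
    nblk <- suppressWarnings(as.integer(f[10]))
    if (anyNA(c(start0, thick0, thick1, nblk)))
      stop("read_gene_models: malformed BED12 at line ", i, " of ", path)
    sizes <- as.integer(strsplit(sub(",$", "", f[11]), ",")[[1]])
    offs <- as.integer(strsplit(sub(",$", "", f[12]), ",")[[1]])
    if (length(sizes) != nblk || length(offs) != nblk)
      stop("read_gene_models: block count mismatch at line ", i, " of ", path)
    ex_start <- start0 + offs + 1L           # 0-based half-open -> 1-based
    ex_end <- start0 + offs + sizes
    coding <- thick1 > thick0
    out[[i]] <- gene_model(
      transcript_id = f[4], gene_name = f[4], chrom = chrom, strand = f[6],
      exon_start = ex_start, exon_end = ex_end,
      cds_start = if (coding) thick0 + 1L else NA_integer_,
      cds_end = if (coding) thick1 else NA_integer_
    )
  }
  out
}

.read_models_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e)
                   stop("read_gene_models: parse error in ", path, ": ",
                        conditionMessage(e)))
  if (length(gr) == 0L) return(list())
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gname <- if (!is.null(md$gene_name)) as.character(md$gene_name)
           else if (!is.null(md$gene_id)) as.character(md$gene_id) else tid
  type <- as.character(md$type)
  keep <- type %in% c("exon", "CDS") & !is.na(tid)
  gr <- gr[keep]; tid <- tid[keep]; gname <- gname[keep]; type <- type[keep]
  models <- list()
  for (t in unique(tid)) {
    sel <- tid == t
    ex <- sel & type == "exon"
    cds <- sel & type == "CDS"
    if (!any(ex)) ex <- cds  # transcripts annotated by CDS features only
    models[[t]] <- gene_model(
      transcript_id = t,
      gene_name = gname[sel][1],
      chrom = as.character(GenomicRanges::seqnames(gr[ex]))[1],
      strand = as.character(GenomicRanges::strand(gr[ex]))[1],
      exon_start = GenomicRanges::start(gr[ex]),
      exon_end = GenomicRanges::end(gr[ex]),
      cds_start = if (any(cds)) min(GenomicRanges::start(gr[cds])) else NA_integer_,
      cds_end = if (any(cds)) max(GenomicRanges::end(gr[cds])) else NA_integer_
    )
  }
  unname(models)
}

#' Write gene models as BED12
#' @param models List of `gene_model` objects.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(models, path) {
  lines <- vapply(models, function(m) {
    start0 <- min(m$exon_start) - 1L
    end1 <- max(m$exon_end)
    sizes <- m$exon_end - m$exon_start + 1L
    offs <- m$exon_start - 1L - start0
    coding <- !is.na(m$cds_start)
    paste(m$chrom, start0, end1, m$transcript_id, 0L, m$strand,
          if (coding) m$cds_start - 1L else start0,
          if (coding) m$cds_end else start0,
          0L, length(sizes),
          paste0(paste(sizes, collapse = ","), ","),
          paste0(paste(offs, collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Published coding-region editing candidate tables
#'
#' The two published candidate tables bundled with the package: significant
#' A-to-G sites in coding regions from a pooled human brain RNA-seq study
#' (with codon consequences) and from a single-individual spinal-cord
#' RNA-seq experiment with matched exome base counts. Counts columns are in
#' A,C,G,T order; `bcr_*` are quality-filtered RNA base counts, `bcrf_*`
#' unfiltered ones, `bce_*` quality-filtered exome counts.
#'
#' @param which `"brain"` or `"spinal_cord"`.
#' @return data.frame of published rows.
#' @export
published_sites <- function(which = c("brain", "spinal_cord")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0(which, "_coding_sites.tsv"),
                   package = "editcall", mustWork = TRUE)
  utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
}

# ---- SNP table -------------------------------------------------------------

#' Read a known-SNP position table
#'
#' Two whitespace- or tab-separated columns: chromosome and 1-based position,
#' with an optional header line. Duplicate rows collapse (set semantics).
#'
#' @param path Text file.
#' @return An object of class `snp_table`.
#' @export
read_snp_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) return(snp_table(character(0), integer(0)))
  f1 <- strsplit(trimws(lines[1]), "[\t ]+")[[1]]
  has_header <- length(f1) >= 2L &&
    is.na(suppressWarnings(as.integer(f1[2]))) &&
    grepl("pos|start|coord", tolower(f1[2]))
  if (has_header) lines <- lines[-1L]
  if (length(lines) == 0L) return(snp_table(character(0), integer(0)))
  parts <- strsplit(trimws(lines), "[\t ]+")
  chrom <- vapply(parts, `[`, character(1), 1L)
  posc <- vapply(parts, `[`, character(1), 2L)
  pos <- suppressWarnings(as.integer(posc))
  if (anyNA(pos))
    stop("read_snp_table: non-integer position at data line ",
         which(is.na(pos))[1], " of ", path)
  snp_table(chrom, pos)
}

#' Construct a SNP position table
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @return An object of class `snp_table` supporting [snp_contains()] and
#'   `length()`.
#' @export
snp_table <- function(chrom = character(0), pos = integer(0)) {
  keys <- unique(paste(chrom, as.integer(pos), sep = ":"))
  if (length(chrom) == 0L) keys <- character(0)
  structure(list(keys = keys), class = "snp_table")
}

#' @export
length.snp_table <- function(x) length(x$keys)

#' Membership query on a SNP table
#' @param snps A `snp_table`.
#' @param chrom,pos Vectors of chromosome names and 1-based positions.
#' @return Logical vector.
#' @export
snp_contains <- function(snps, chrom, pos) {
  paste(chrom, as.integer(pos), sep = ":") %in% snps$keys
}

#' @export
print.snp_table <- function(x, ...) {
  cat("<snp_table> ", length(x$keys), " positions\n", sep = "")
  invisible(x)
}

# ---- SAM -------------------------------------------------------------------

#' Read alignments from a text SAM file
#'
#' Parses the 11 mandatory SAM fields plus the NH tag (mapping multiplicity).
#' Other optional tags are ignored. FLAG bits are decoded into logical
#' columns; the duplicate flag (0x400) is honored downstream.
#'
#' @param path SAM file.
#' @return data.frame of alignment records with columns qname, flag, rname,
#'   pos, mapq, cigar, rnext, pnext, tlen, seq, qual, nh, plus decoded
#'   strand, paired, mate1/mate2, duplicate and unique columns.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^@", lines) & nzchar(lines)]
  if (length(lines) == 0L) return(empty_sam())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 11L))
    stop("read_sam: malformed SAM record at alignment line ",
         which(nf < 11L)[1], " of ", path)
  fld <- function(i) vapply(parts, `[`, character(1), i)
  nh <- vapply(parts, function(p) {
    tag <- grep("^NH:i:", p[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else 1L
  }, integer(1))
  df <- data.frame(
    qname = fld(1), flag = as.integer(fld(2)), rname = fld(3),
    pos = as.integer(fld(4)), mapq = as.integer(fld(5)), cigar = fld(6),
    rnext = fld(7), pnext = as.integer(fld(8)), tlen = as.integer(fld(9)),
    seq = toupper(fld(10)), qual = fld(11), nh = nh,
    stringsAsFactors = FALSE
  )
  decode_sam_flags(df)
}

#' Decode SAM FLAG bits into logical columns
#' @param df Alignment data.frame with a `flag` column.
#' @return The data.frame with strand, paired, mate1, mate2, duplicate,
#'   unmapped and unique columns added or refreshed.
#' @export
decode_sam_flags <- function(df) {
  f <- df$flag
  df$paired <- bitwAnd(f, 0x1) > 0L
  df$unmapped <- bitwAnd(f, 0x4) > 0L
  df$strand <- ifelse(bitwAnd(f, 0x10) > 0L, "-", "+")
  df$mate1 <- !df$paired | bitwAnd(f, 0x40) > 0L
  df$mate2 <- bitwAnd(f, 0x80) > 0L
  df$duplicate <- bitwAnd(f, 0x400) > 0L
  secondary <- bitwAnd(f, 0x100) > 0L
  df$unique <- !secondary & (is.null(df$nh) | df$nh <= 1L)
  df
}

#' An empty alignment data.frame
#' @return Zero-row alignment data.frame with the standard columns.
#' @export
empty_sam <- function() {
  decode_sam_flags(data.frame(
    qname = character(0), flag = integer(0), rname = character(0),
    pos = integer(0), mapq = integer(0), cigar = character(0),
    rnext = character(0), pnext = integer(0), tlen = integer(0),
    seq = character(0), qual = character(0), nh = integer(0),
    stringsAsFactors = FALSE
  ))
}

#' Write alignments to a text SAM file
#' @param aln Alignment data.frame as from [read_sam()].
#' @param path Output file.
#' @param genome Optional genome (named sequences) used to emit `@SQ` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  if (!is.null(genome))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)), con)
  if (nrow(aln) > 0L) {
    nh <- if (is.null(aln$nh)) rep(1L, nrow(aln)) else aln$nh
    writeLines(paste(aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                     aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq,
                     aln$qual, paste0("NH:i:", nh), sep = "\t"), con)
  }
  invisible(path)
}

# ---- candidate table -------------------------------------------------------

.fmt_counts <- function(a, c, g, t) sprintf("[%d, %d, %d, %d]", a, c, g, t)

.parse_counts <- function(s) {
  v <- lapply(strsplit(gsub("\\[|\\]| ", "", s), ","), as.integer)
  do.call(rbind, v)
}

#' Write the candidate-site table
#'
#' Tab-separated, one row per candidate sorted by ascending p-value: Position,
#' Gene, Ref, ST, CC, AAC, CodP, CovR, BCR (quality-filtered base counts
#' A,C,G,T), BCR-F (unfiltered counts), \%Editing, Pvalue, FDR. When DNA
#' evidence columns are present on the candidates (see
#' [validate_candidates()]) CovE, BCE, Status and LLR are appended. Header
#' metadata lines are prefixed with '#'.
#'
#' @param candidates Candidate data.frame from [call_candidates()].
#' @param path Output file.
#' @param header_lines Optional character vector of metadata lines (without
#'   the leading '#').
#' @return `path`, invisibly.
#' @export
write_candidate_table <- function(candidates, path, header_lines = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_lines))
    writeLines(paste0("# ", header_lines), con)
  with_dna <- !is.null(candidates$cov_dna)
  cols <- c("Position", "Gene", "Ref", "ST", "CC", "AAC", "CodP", "CovR",
            "BCR[A,C,G,T]", "BCR-F[A,C,G,T]", "%Editing", "Pvalue", "FDR")
  if (with_dna) cols <- c(cols, "CovE", "BCE[A,C,G,T]", "Status", "LLR")
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(candidates) > 0L) {
    o <- order(candidates$p_value, candidates$chrom, candidates$pos)
    cd <- candidates[o, , drop = FALSE]
    row <- paste(
      paste0(cd$chrom, ":", cd$pos), cd$gene, cd$ref, cd$st,
      ifelse(is.na(cd$cc), "-", cd$cc), ifelse(is.na(cd$aac), "-", cd$aac),
      ifelse(is.na(cd$codp), "-", cd$codp), cd$coverage,
      .fmt_counts(cd$A, cd$C, cd$G, cd$T),
      .fmt_counts(cd$raw_A, cd$raw_C, cd$raw_G, cd$raw_T),
      sprintf("%.2f", 100 * cd$editing_fraction),
      sprintf("%.3e", cd$p_value), sprintf("%.3e", cd$fdr),
      sep = "\t")
    if (with_dna) {
      row <- paste(row, cd$cov_dna,
                   .fmt_counts(cd$dna_A, cd$dna_C, cd$dna_G, cd$dna_T),
                   cd$status,
                   ifelse(is.na(cd$llr), "ND", sprintf("%.2f", cd$llr)),
                   sep = "\t")
    }
    writeLines(row, con)
  }
  invisible(path)
}

#' Read a candidate-site table written by [write_candidate_table()]
#' @param path Candidate TSV file.
#' @return Candidate data.frame (numeric fields recovered to printed
#'   precision).
#' @export
read_candidate_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  header <- strsplit(lines[1], "\t")[[1]]
  lines <- lines[-1]
  with_dna <- "CovE" %in% header
  if (length(lines) == 0L) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      gene = character(0), ref = character(0),
                      st = character(0), cc = character(0), aac = character(0),
                      codp = integer(0), coverage = integer(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), raw_A = integer(0), raw_C = integer(0),
                      raw_G = integer(0), raw_T = integer(0),
                      editing_fraction = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), stringsAsFactors = FALSE)
    return(out)
  }
  parts <- do.call(rbind, strsplit(lines, "\t"))
  posf <- strsplit(parts[, 1], ":")
  bcr <- .parse_counts(parts[, 9])
  bcrf <- .parse_counts(parts[, 10])
  out <- data.frame(
    chrom = vapply(posf, `[`, character(1), 1L),
    pos = as.integer(vapply(posf, `[`, character(1), 2L)),
    gene = parts[, 2], ref = parts[, 3], st = parts[, 4],
    cc = ifelse(parts[, 5] == "-", NA_character_, parts[, 5]),
    aac = ifelse(parts[, 6] == "-", NA_character_, parts[, 6]),
    codp = suppressWarnings(as.integer(parts[, 7])),
    coverage = as.integer(parts[, 8]),
    A = bcr[, 1], C = bcr[, 2], G = bcr[, 3], T = bcr[, 4],
    raw_A = bcrf[, 1], raw_C = bcrf[, 2], raw_G = bcrf[, 3],
    raw_T = bcrf[, 4],
    editing_fraction = as.numeric(parts[, 11]) / 100,
    p_value = as.numeric(parts[, 12]),
    fdr = as.numeric(parts[, 13]),
    stringsAsFactors = FALSE
  )
  if (with_dna) {
    bce <- .parse_counts(parts[, 15])
    out$cov_dna <- as.integer(parts[, 14])
    out$dna_A <- bce[, 1]; out$dna_C <- bce[, 2]
    out$dna_G <- bce[, 3]; out$dna_T <- bce[, 4]
    out$status <- parts[, 16]
    out$llr <- suppressWarnings(as.numeric(parts[, 17]))
  }
  out
}
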