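#' Phred values of a quality string
#' @param qual SAM/FASTQ quality string(s), Phred+33.
#' @return For a single string, integer vector of per-base qualities; for a
#'   vector, a list of integer vectors.
#' @export
phred_values <- function(qual) {
  out <- lapply(qual, function(q) utf8ToInt(q) - 33L)
  if (length(out) == 1L) out[[1]] else out
}

#' Phred string from integer qualities
#' @param q Integer vector of Phred values.
#' @return Character scalar (Phred+33 encoding).
#' @export
phred_string <- function(q) intToUtf8(as.integer(q) + 33L)

#' Prefilter reads on N content and mean base quality
#'
#' Retains exactly the records with at most `max_n` N characters and mean
#' Phred quality at least `min_mean_quality`; input order is preserved. Works
#' on genome-space alignment data.frames (columns seq/qual) and on
#' transcript-space alignment data.frames (columns bases/quals).
#'
#' @param records Alignment data.frame.
#' @param max_n Maximum allowed N count per read (default 2).
#' @param min_mean_quality Minimum mean Phred quality (default 20). The
#'   cutoff for "very low quality" is not standardized; a mean-based rule is
#'   stable across 50-101 bp reads.
#' @return The retained records, same columns and order.
#' @export
prefilter_reads <- function(records, max_n = 2L, min_mean_quality = 20) {
  if (nrow(records) == 0L) return(records)
  seqcol <- if (!is.null(records$seq)) records$seq else records$bases
  qualcol <- if (!is.null(records$qual)) records$qual else records$quals
  n_count <- nchar(seqcol) - nchar(gsub("N", "", seqcol, fixed = TRUE))
  meanq <- vapply(qualcol, function(q) mean(utf8ToInt(q) - 33L), numeric(1),
                  USE.NAMES = FALSE)
  records[n_count <= max_n & meanq >= min_mean_quality, , drop = FALSE]
}

# ---- CIGAR / block helpers -------------------------------------------------

#' Reference-space blocks of alignments
#'
#' Aligned (M/=/X) stretches in genome coordinates, 1-based inclusive,
#' skipping N (introns) and D (deletions).
#'
#' @param cigar Character vector of CIGAR strings.
#' @param pos Integer vector of 1-based leftmost positions.
#' @return Character vector encoding each record's blocks as
#'   `"start-end,start-end"`.
#' @export
cigar_blocks <- function(cigar, pos) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X"), drop.empty.ranges = TRUE,
    reduce.ranges = TRUE)
  s <- unlist(IRanges::start(rng), use.names = FALSE)
  e <- unlist(IRanges::end(rng), use.names = FALSE)
  grp <- factor(rep(seq_along(cigar), S4Vectors::elementNROWS(rng)),
                levels = seq_along(cigar))
  unname(vapply(split(paste0(s, "-", e), grp), paste, character(1),
                collapse = ","))
}

.blocks_string <- function(start, end) {
  paste(start, end, sep = "-", collapse = ",")
}

.parse_blocks <- function(s) {
  p <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], "-", fixed = TRUE)
  data.frame(start = as.integer(vapply(p, `[`, character(1), 1L)),
             end = as.integer(vapply(p, `[`, character(1), 2L)))
}

#' CIGAR string for a set of genomic blocks
#' @param start,end Integer vectors of block boundaries, sorted, disjoint.
#' @return CIGAR with M for blocks and N for gaps.
#' @export
blocks_to_cigar <- function(start, end) {
  n <- length(start)
  parts <- sprintf("%dM", end - start + 1L)
  if (n > 1L) {
    gaps <- sprintf("%dN", start[-1L] - end[-n] - 1L)
    parts <- c(rbind(parts[-n], gaps), parts[n])
  }
  paste(parts, collapse = "")
}

# ---- transcript-space alignments and projection ----------------------------

#' Construct transcript-space alignment records
#' @param read_id Read identifiers (for paired reads use a `/1` or `/2`
#'   suffix on a shared fragment name).
#' @param transcript_id Transcript each read aligns to.
#' @param start 1-based start in transcript coordinates.
#' @param bases,quals Aligned bases and Phred+33 quality strings.
#' @param read_strand Strand of the read relative to the transcript
#'   (`"+"` for sense).
#' @param unique Logical, uniquely mapping.
#' @return data.frame of transcript alignments.
#' @export
transcript_alignment <- function(read_id, transcript_id, start, bases, quals,
                                 read_strand = "+", unique = TRUE) {
  stopifnot(all(nchar(bases) == nchar(quals)))
  data.frame(read_id = read_id, transcript_id = transcript_id,
             start = as.integer(start), bases = toupper(bases), quals = quals,
             read_strand = read_strand, unique = unique,
             stringsAsFactors = FALSE)
}

#' Project a transcript-space alignment to genome coordinates
#'
#' Transcript position k maps to the k-th exonic base in genomic order for
#' plus-strand models and to the k-th exonic base counting down from the
#' highest genomic coordinate for minus-strand models. Blocks are split at
#' exon boundaries; the reported strand composes the read strand with the
#' model strand. Base and quality slices are returned in genome (plus-strand)
#' orientation.
#'
#' @param ta One-row transcript alignment data.frame (see
#'   [transcript_alignment()]).
#' @param model The matching [gene_model()].
#' @return A list of class `projected_alignment` with fields read_id, chrom,
#'   strand, block_start, block_end, bases, quals, unique.
#' @export
project_to_genome <- function(ta, model) {
  if (is.data.frame(ta)) {
    stopifnot(nrow(ta) == 1L)
    ta <- as.list(ta)
  }
  if (!identical(ta$transcript_id, model$transcript_id))
    stop("project_to_genome: transcript/model mismatch (",
         ta$transcript_id, " vs ", model$transcript_id, ")")
  len <- nchar(ta$bases)
  txlen <- transcript_length(model)
  if (ta$start < 1L || ta$start + len - 1L > txlen)
    stop("project_to_genome: alignment overruns transcript ",
         model$transcript_id)
  gpos <- genome_positions(model)[seq.int(ta$start, ta$start + len - 1L)]
  bases <- ta$bases; quals <- ta$quals
  if (model$strand == "-") {       # genome orientation
    gpos <- rev(gpos)
    bases <- revcomp(bases)
    quals <- intToUtf8(rev(utf8ToInt(quals)))
  }
  brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
  bs <- gpos[brk[-length(brk)] + 1L]
  be <- gpos[brk[-1L]]
  off <- brk[-length(brk)]
  w <- be - bs + 1L
  read_strand <- if (is.null(ta$read_strand)) "+" else ta$read_strand
  strand <- if (read_strand == "+") model$strand
            else if (model$strand == "+") "-" else "+"
  structure(list(
    read_id = ta$read_id, chrom = model$chrom, strand = strand,
    block_start = bs, block_end = be,
    bases = substring(bases, off + 1L, off + w),
    quals = substring(quals, off + 1L, off + w),
    unique = if (is.null(ta$unique)) TRUE else ta$unique
  ), class = "projected_alignment")
}

#' Project a set of transcript alignments
#' @param tx_aln Transcript alignment data.frame.
#' @param models List of gene models (matched by transcript_id).
#' @return data.frame with read_id, chrom, strand, blocks (encoded
#'   `"start-end,..."`), bases, quals, unique.
#' @export
project_alignments <- function(tx_aln, models) {
  names(models) <- vapply(models, `[[`, character(1), "transcript_id")
  n <- nrow(tx_aln)
  if (n == 0L)
    return(data.frame(read_id = character(0), chrom = character(0),
                      strand = character(0), blocks = character(0),
                      bases = character(0), quals = character(0),
                      unique = logical(0), stringsAsFactors = FALSE))
  if (!all(tx_aln$transcript_id %in% names(models)))
    stop("project_alignments: no model for ",
         setdiff(tx_aln$transcript_id, names(models))[1])
  gmaps <- lapply(models, genome_positions)
  mstrand <- vapply(models, `[[`, character(1), "strand")
  mchrom <- vapply(models, `[[`, character(1), "chrom")
  tid <- tx_aln$transcript_id
  len <- nchar(tx_aln$bases)
  txlen <- vapply(models, transcript_length, integer(1))[tid]
  if (any(tx_aln$start < 1L | tx_aln$start + len - 1L > txlen))
    stop("project_alignments: alignment overruns transcript")
  minus <- mstrand[tid] == "-"
  read_strand <- if (is.null(tx_aln$read_strand)) rep("+", n)
                 else tx_aln$read_strand
  strand <- ifelse(xor(read_strand == "-", minus), "-", "+")
  # genome-orientation base/quality strings (reverse-complement for - genes)
  bases <- tx_aln$bases
  quals <- tx_aln$quals
  if (any(minus)) {
    bases[minus] <- revcomp(bases[minus])
    quals[minus] <- vapply(quals[minus], function(q)
      intToUtf8(rev(utf8ToInt(q))), character(1), USE.NAMES = FALSE)
  }
  blocks <- character(n)
  for (i in seq_len(n)) {
    gpos <- gmaps[[tid[i]]][seq.int(tx_aln$start[i],
                                    tx_aln$start[i] + len[i] - 1L)]
    if (minus[i]) gpos <- rev(gpos)
    brk <- c(0L, which(diff(gpos) != 1L), length(gpos))
    blocks[i] <- .blocks_string(gpos[brk[-length(brk)] + 1L], gpos[brk[-1L]])
  }
  data.frame(read_id = tx_aln$read_id, chrom = unname(mchrom[tid]),
             strand = strand, blocks = blocks, bases = bases, quals = quals,
             unique = if (is.null(tx_aln$unique)) TRUE else tx_aln$unique,
             stringsAsFactors = FALSE)
}

#' Exon-exon junctions implied by gene models
#' @param models List of gene models.
#' @return data.frame with columns chrom, donor (1-based end of the upstream
#'   exon in genomic order), acceptor (1-based start of the downstream exon)
#'   and strand; deduplicated across transcripts.
#' @export
junctions_from_models <- function(models) {
  rows <- lapply(models, function(m) {
    k <- length(m$exon_start)
    if (k < 2L) return(NULL)
    data.frame(chrom = m$chrom, donor = m$exon_end[-k],
               acceptor = m$exon_start[-1L], strand = m$strand,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}

#' Write a junction set as a donor/acceptor TSV
#' @param junctions data.frame from [junctions_from_models()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(junctions, path) {
  utils::write.table(junctions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# ---- concordance -----------------------------------------------------------

.sam_read_key <- function(aln) {
  ifelse(aln$paired,
         paste0(aln$qname, "/", ifelse(aln$mate2, "2", "1")),
         aln$qname)
}

#' Keep genome alignments concordant with projected transcriptome alignments
#'
#' A genome-space record is retained when the same read (keyed by read id and
#' mate index) was uniquely aligned in transcriptome space and its projected
#' genomic location -- chromosome, strand and the exact set of aligned blocks
#' -- is identical to the direct genome alignment. Reads unique in neither
#' space, or placed at different loci by the two alignments (e.g. paralogous
#' gene copies), are removed. For paired reads both mates must be concordant
#' or the whole pair is dropped.
#'
#' @param projected Projection table from [project_alignments()].
#' @param genomic Genome-space alignment data.frame (from [read_sam()]).
#' @return Subset of `genomic`.
#' @export
concordance_filter <- function(projected, genomic) {
  if (nrow(genomic) == 0L) return(genomic)
  if (nrow(projected) == 0L) return(genomic[0L, , drop = FALSE])
  proj <- projected[projected$unique, , drop = FALSE]
  proj_key <- paste(proj$read_id, proj$chrom, proj$strand, proj$blocks,
                    sep = "|")
  gen_blocks <- cigar_blocks(genomic$cigar, genomic$pos)
  gen_key <- paste(.sam_read_key(genomic), genomic$rname, genomic$strand,
                   gen_blocks, sep = "|")
  ok <- genomic$unique & !genomic$unmapped & gen_key %in% proj_key
  # both mates of a pair must be concordant
  keep_q <- tapply(ok, genomic$qname, all)
  ok <- ok & unname(keep_q[genomic$qname])
  genomic[ok, , drop = FALSE]
}
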