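#' Gene model constructor
#'
#' A gene model describes one transcript: its chromosome, strand, ordered
#' exons and (for coding transcripts) the genomic CDS interval. All
#' coordinates are 1-based inclusive.
#'
#' @param transcript_id Transcript identifier.
#' @param gene_name Gene symbol (defaults to the transcript id).
#' @param chrom Chromosome name. Matching elsewhere is exact string equality;
#'   no "chr" aliasing is ever applied.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Integer vectors of exon boundaries, 1-based
#'   inclusive, sorted by genomic start and non-overlapping.
#' @param cds_start,cds_end Genomic CDS interval, or `NA` for a non-coding
#'   transcript. The interval must lie inside the exon union and the spliced
#'   CDS length must be divisible by 3.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(transcript_id, gene_name = transcript_id, chrom, strand,
                       exon_start, exon_end,
                       cds_start = NA_integer_, cds_end = NA_integer_) {
  exon_start <- as.integer(exon_start)
  exon_end <- as.integer(exon_end)
  stopifnot(length(exon_start) == length(exon_end), length(exon_start) >= 1L)
  o <- order(exon_start)
  exon_start <- exon_start[o]; exon_end <- exon_end[o]
  if (any(exon_end < exon_start))
    stop("gene_model: exon end before exon start for ", transcript_id)
  if (length(exon_start) > 1L &&
      any(exon_start[-1L] <= exon_end[-length(exon_end)]))
    stop("gene_model: overlapping exons in ", transcript_id)
  if (!strand %in% c("+", "-"))
    stop("gene_model: strand must be '+' or '-'")
  m <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_name = as.character(gene_name),
    chrom = as.character(chrom),
    strand = strand,
    exon_start = exon_start,
    exon_end = exon_end,
    cds_start = as.integer(cds_start),
    cds_end = as.integer(cds_end)
  ), class = "gene_model")
  if (!is.na(m$cds_start)) {
    if (is.na(m$cds_end) || m$cds_end < m$cds_start)
      stop("gene_model: bad CDS interval for ", transcript_id)
    ends_exonic <- vapply(c(m$cds_start, m$cds_end), function(p)
      any(p >= m$exon_start & p <= m$exon_end), logical(1))
    if (!all(ends_exonic))
      stop("gene_model: CDS boundaries not exonic for ", transcript_id)
    # a CDS whose spliced length is not a codon multiple is tolerated here
    # (real annotations contain them); codon_effect() refuses to use one
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding" else
    paste0("CDS ", x$cds_start, "-", x$cds_end)
  cat(sprintf("<gene_model> %s (%s) %s:%s [%s] %s\n", x$transcript_id,
              x$gene_name, x$chrom, x$strand,
              paste(x$exon_start, x$exon_end, sep = "-", collapse = ","), cds))
  invisible(x)
}

#' Exon lengths and spliced transcript length
#' @param model A `gene_model`.
#' @return Integer vector of exon lengths / total spliced length.
#' @export
transcript_length <- function(model) {
  sum(model$exon_end - model$exon_start + 1L)
}

#' Spliced CDS length of a coding model
#' @param model A `gene_model`.
#' @return Integer number of coding bases (0 for non-coding models).
#' @export
cds_spliced_length <- function(model) {
  if (is.na(model$cds_start)) return(0L)
  s <- pmax(model$exon_start, model$cds_start)
  e <- pmin(model$exon_end, model$cds_end)
  sum(pmax(e - s + 1L, 0L))
}

#' Map transcript coordinates to genome coordinates
#'
#' Position k in transcript coordinates (1-based, 5' to 3' on the transcribed
#' strand) maps to the k-th exonic base in genomic order for plus-strand
#' models, and to the k-th exonic base counting down from the highest genomic
#' coordinate for minus-strand models.
#'
#' @param model A `gene_model`.
#' @param tx_pos Integer vector of transcript positions.
#' @return Integer vector of genomic positions.
#' @export
tx_to_genome <- function(model, tx_pos) {
  tx_pos <- as.integer(tx_pos)
  n <- transcript_length(model)
  if (any(tx_pos < 1L | tx_pos > n))
    stop("tx_to_genome: transcript position outside [1, ", n, "]")
  gmap <- genome_positions(model)
  gmap[tx_pos]
}

#' Map genome coordinates to transcript coordinates
#' @param model A `gene_model`.
#' @param g_pos Integer vector of genomic positions (must be exonic).
#' @return Integer vector of transcript positions.
#' @export
genome_to_tx <- function(model, g_pos) {
  gmap <- genome_positions(model)
  idx <- match(as.integer(g_pos), gmap)
  if (anyNA(idx))
    stop("genome_to_tx: position not exonic in ", model$transcript_id)
  idx
}

#' Exonic genome positions in transcript order
#' @param model A `gene_model`.
#' @return Integer vector, element k is the genomic position of transcript
#'   base k.
#' @export
genome_positions <- function(model) {
  gmap <- unlist(Map(seq.int, model$exon_start, model$exon_end),
                 use.names = FALSE)
  if (model$strand == "-") gmap <- rev(gmap)
  gmap
}

#' Spliced transcript sequence (transcribed-strand orientation)
#' @param model A `gene_model`.
#' @param genome A genome as returned by [read_genome()].
#' @return Character scalar, the mRNA sequence in 5'->3' orientation.
#' @export
transcript_seq <- function(model, genome) {
  pieces <- substring(genome[[model$chrom]], model$exon_start, model$exon_end)
  s <- paste(pieces, collapse = "")
  if (model$strand == "-") s <- revcomp(s)
  s
}

#' CDS interval in transcript coordinates
#' @param model A coding `gene_model`.
#' @return Integer length-2 vector `c(start, end)` in transcript coordinates.
#' @export
cds_tx_interval <- function(model) {
  if (is.na(model$cds_start)) stop("cds_tx_interval: non-coding model")
  ends <- if (model$strand == "+") c(model$cds_start, model$cds_end)
          else c(model$cds_end, model$cds_start)
  sort(genome_to_tx(model, ends))
}

#' Reverse complement of a nucleotide string
#' @param s Character vector of sequences over A,C,G,T,N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Complement of single bases
#' @param b Character vector of single bases.
#' @return Complemented bases.
#' @export
comp_base <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[b])
}
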