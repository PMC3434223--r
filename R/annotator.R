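#' Assign a genomic position to a gene region
#'
#' Classifies a position against a set of gene models: inside the CDS of a
#' reference transcript -> `CDS`; exonic in a reference transcript but
#' upstream/downstream of the CDS (strand-aware) -> `UTR5`/`UTR3`; exonic
#' only in transcripts outside the designated reference set -> `alt-exon`;
#' within a gene span but not exonic -> `intron`; otherwise `intergenic`.
#' When several reference transcripts disagree, CDS wins and the reporting
#' transcript is the one with the longest CDS.
#'
#' @param chrom,pos Position (1-based).
#' @param models List of gene models.
#' @param reference_set Optional character vector of transcript ids that form
#'   the reference annotation (e.g. the RefSeq subset); defaults to all
#'   models. Exons present only outside this set are "alternative exons".
#' @param repeat_intervals Optional data.frame (chrom, start, end, 1-based
#'   inclusive) of repeat elements; overlap sets the repeat flag.
#' @return List with gene, transcript_id, region, strand, repeat_overlap.
#' @export
assign_region <- function(chrom, pos, models, reference_set = NULL,
                          repeat_intervals = NULL) {
  pos <- as.integer(pos)
  if (is.null(reference_set))
    reference_set <- vapply(models, `[[`, character(1), "transcript_id")
  rep_flag <- FALSE
  if (!is.null(repeat_intervals) && nrow(repeat_intervals) > 0L)
    rep_flag <- any(repeat_intervals$chrom == chrom &
                    repeat_intervals$start <= pos &
                    repeat_intervals$end >= pos)
  hit <- function(region, m) list(gene = m$gene_name,
                                  transcript_id = m$transcript_id,
                                  region = region, strand = m$strand,
                                  repeat_overlap = rep_flag)
  best_cds <- NULL; best_cds_len <- -1L
  best_utr <- NULL; alt_hit <- NULL; intron_hit <- NULL
  for (m in models) {
    if (m$chrom != chrom) next
    in_span <- pos >= min(m$exon_start) && pos <= max(m$exon_end)
    if (!in_span) next
    exonic <- any(pos >= m$exon_start & pos <= m$exon_end)
    is_ref <- m$transcript_id %in% reference_set
    if (!exonic) {
      if (is.null(intron_hit) && is_ref) intron_hit <- hit("intron", m)
      next
    }
    if (!is_ref) {
      if (is.null(alt_hit)) alt_hit <- hit("alt-exon", m)
      next
    }
    coding <- !is.na(m$cds_start)
    if (coding && pos >= m$cds_start && pos <= m$cds_end) {
      len <- cds_spliced_length(m)
      if (len > best_cds_len) { best_cds <- hit("CDS", m); best_cds_len <- len }
    } else if (coding) {
      before <- pos < m$cds_start
      region <- if ((before && m$strand == "+") || (!before && m$strand == "-"))
        "UTR5" else "UTR3"
      if (is.null(best_utr)) best_utr <- hit(region, m)
    } else {
      # exonic in a non-coding reference transcript: treat as alt-exon
      if (is.null(alt_hit)) alt_hit <- hit("alt-exon", m)
    }
  }
  res <- best_cds
  if (is.null(res)) res <- best_utr
  if (is.null(res)) res <- alt_hit
  if (is.null(res)) res <- intron_hit
  if (is.null(res))
    res <- list(gene = NA_character_, transcript_id = NA_character_,
                region = "intergenic", strand = NA_character_,
                repeat_overlap = rep_flag)
  res
}

#' Codon-level consequence of an A-to-G edit
#'
#' Locates the codon containing a CDS position in spliced CDS coordinates
#' (strand-aware; minus-strand genes are reverse-complemented), substitutes
#' the edited base on the transcribed strand, and translates both codons with
#' the standard genetic code.
#'
#' @param chrom,pos Site coordinates; must lie in the CDS of `model`.
#' @param model A coding [gene_model()].
#' @param genome Genome from [read_genome()].
#' @param alt_base The substituted base in genome orientation (G for
#'   plus-strand genes, C for minus-strand genes for A-to-I editing).
#' @return List with codon_position (1-3), ref_codon, alt_codon, ref_aa,
#'   alt_aa, synonymous.
#' @export
codon_effect <- function(chrom, pos, model, genome, alt_base) {
  pos <- as.integer(pos)
  if (is.na(model$cds_start))
    stop("codon_effect: non-coding model ", model$transcript_id)
  if (model$chrom != chrom || pos < model$cds_start || pos > model$cds_end ||
      !any(pos >= model$exon_start & pos <= model$exon_end))
    stop("codon_effect: position ", chrom, ":", pos, " not in the CDS of ",
         model$transcript_id)
  cds_iv <- cds_tx_interval(model)
  tx_pos <- genome_to_tx(model, pos)
  k <- tx_pos - cds_iv[1] + 1L          # 1-based position in spliced CDS
  if (cds_spliced_length(model) %% 3L != 0L)
    stop("codon_effect: CDS length not divisible by 3")
  codon_idx <- (k - 1L) %/% 3L          # 0-based codon index
  codon_pos <- (k - 1L) %% 3L + 1L
  tx <- transcript_seq(model, genome)
  codon_start <- cds_iv[1] + 3L * codon_idx
  ref_codon <- substring(tx, codon_start, codon_start + 2L)
  alt_tx <- if (model$strand == "+") alt_base else comp_base(alt_base)
  alt_codon <- ref_codon
  substring(alt_codon, codon_pos, codon_pos) <- alt_tx
  ref_aa <- translate_codon(ref_codon)
  alt_aa <- translate_codon(alt_codon)
  list(codon_position = codon_pos, ref_codon = ref_codon,
       alt_codon = alt_codon, ref_aa = ref_aa, alt_aa = alt_aa,
       synonymous = identical(ref_aa, alt_aa))
}

#' Translate one codon with the standard genetic code
#' @param codon Character vector of 3-base codons (DNA alphabet).
#' @return One-letter amino acid codes (`*` for stop).
#' @export
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[toupper(codon)])
}

#' Read repeat intervals from a BED file
#' @param path BED file (0-based half-open); only the first three columns are
#'   used.
#' @return data.frame with chrom, start, end (1-based inclusive).
#' @export
read_repeat_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t| +")
  data.frame(chrom = vapply(parts, `[`, character(1), 1L),
             start = as.integer(vapply(parts, `[`, character(1), 2L)) + 1L,
             end = as.integer(vapply(parts, `[`, character(1), 3L)),
             stringsAsFactors = FALSE)
}
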