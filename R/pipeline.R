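#' Run the full editing-detection pipeline
#'
#' Orchestrates prefilter -> (optional) transcriptome/genome concordance ->
#' pileup -> substitution spectrum -> candidate calling and annotation ->
#' (optional) DNA validation, writing the candidate table and a JSON run
#' manifest. Identical inputs and configuration yield identical outputs.
#'
#' @param rna Genome-space RNA alignments: path to a SAM file or an alignment
#'   data.frame.
#' @param genome Path to a FASTA file or a genome object.
#' @param models Path to a GTF/BED12 file or a list of gene models.
#' @param snps Path to a SNP position table, a `snp_table`, or NULL.
#' @param config A [caller_config()].
#' @param tx_aln Optional transcript-space alignments (data.frame) projected
#'   and compared against `rna` to keep only concordant records.
#' @param dna Optional DNA/exome alignments (path or data.frame) for
#'   validation.
#' @param out_dir Output directory; when NULL nothing is written.
#' @param keep_intermediates Also write the spectrum and prefiltered
#'   alignment audit files (default FALSE).
#' @param prefilter_max_n,prefilter_min_mean_quality Read prefilter settings
#'   (see [prefilter_reads()]).
#' @param reference_set,repeat_intervals Annotation options (see
#'   [assign_region()]).
#' @param min_dna_quality,min_dna_reads DNA validation thresholds.
#' @return The candidate data.frame, invisibly when writing; attributes
#'   `spectrum` and `manifest` carry the spectrum object and the manifest
#'   list.
#' @export
run_detect <- function(rna, genome, models, snps = NULL, config = caller_config(),
                       tx_aln = NULL, dna = NULL, out_dir = NULL,
                       keep_intermediates = FALSE,
                       prefilter_max_n = 2L, prefilter_min_mean_quality = 20,
                       reference_set = NULL, repeat_intervals = NULL,
                       min_dna_quality = 30, min_dna_reads = 5) {
  digests <- list()
  take <- function(x, reader, label) {
    if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
        nchar(x) <= 500L) {
      if (!file.exists(x)) stop("run_detect: missing input ", x)
      digests[[label]] <<- unname(tools::md5sum(x))
      reader(x)
    } else x
  }
  rna <- take(rna, read_sam, "rna")
  genome <- take(genome, read_genome, "genome")
  models <- take(models, read_gene_models, "models")
  snps <- if (is.null(snps)) snp_table() else take(snps, read_snp_table, "snps")
  dna <- if (is.null(dna)) NULL else take(dna, read_sam, "dna")

  rna <- prefilter_reads(rna, max_n = prefilter_max_n,
                         min_mean_quality = prefilter_min_mean_quality)
  if (!is.null(tx_aln)) {
    proj <- project_alignments(tx_aln, models)
    rna <- concordance_filter(proj, rna)
  }
  if (config$end_trim > 0L) rna <- trim_read_ends(rna, config$end_trim)
  sites <- pileup(rna, genome, min_quality = config$min_base_quality)
  spectrum <- build_spectrum(sites, snps)
  cand <- call_candidates(sites, spectrum, snps, models, config,
                          genome = genome, reference_set = reference_set,
                          repeat_intervals = repeat_intervals)
  if (!is.null(dna) && nrow(cand) > 0L)
    cand <- validate_candidates(cand, dna, rna_aln = rna,
                                min_dna_quality = min_dna_quality,
                                min_dna_reads = min_dna_reads,
                                min_rna_quality = config$min_base_quality)
  manifest <- list(
    tool = "editcall",
    version = as.character(utils::packageVersion("editcall")),
    config = unclass(config),
    prefilter = list(max_n = prefilter_max_n,
                     min_mean_quality = prefilter_min_mean_quality),
    dna_thresholds = list(min_quality = min_dna_quality,
                          min_reads = min_dna_reads),
    inputs = digests,
    n_alignments = nrow(rna), n_sites = nrow(sites),
    n_candidates = nrow(cand),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    hdr <- c(paste0("editcall v", manifest$version),
             sprintf("min_base_quality=%g min_coverage=%g min_editing=%g fdr=%g region=%s stranded=%s",
                     config$min_base_quality, config$min_coverage,
                     config$min_editing_fraction, config$fdr_threshold,
                     config$region, config$stranded))
    write_candidate_table(cand, file.path(out_dir, "candidates.tsv"),
                          header_lines = hdr)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (keep_intermediates) {
      write_spectrum(spectrum, file.path(out_dir, "spectrum.tsv"))
      write_sam(rna, file.path(out_dir, "alignments_used.sam"),
                genome = genome)
    }
  }
  attr(cand, "spectrum") <- spectrum
  attr(cand, "manifest") <- manifest
  if (is.null(out_dir)) cand else invisible(cand)
}
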