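#' DNA (exome) base counts at a site
#'
#' Pileup counts from genome-space DNA alignments at a single position,
#' excluding duplicate-flagged records (PCR artefacts) and counting only
#' bases with Phred quality at least `min_quality` in the filtered columns.
#'
#' @param dna_aln DNA alignment data.frame.
#' @param chrom,pos Site coordinates (1-based).
#' @param ref_base Reference base at the site.
#' @param min_quality Minimum Phred base quality (default 30).
#' @return One-row data.frame as from [pileup_site_counts()].
#' @export
dna_site_counts <- function(dna_aln, chrom, pos, ref_base, min_quality = 30) {
  obs <- site_observations(dna_aln, chrom, pos, exclude_duplicates = TRUE)
  pileup_site_counts(obs, ref_base, min_quality = min_quality)
}

#' Homozygous-reference rule for exome evidence
#'
#' A site is homozygous reference when at least `min_reads` quality-filtered
#' DNA reads cover it and every one of them carries the reference base --
#' excluding a genomic (SNP) explanation for the RNA mismatch.
#'
#' @param sc One-row site-count data.frame (filtered columns A,C,G,T at the
#'   DNA quality threshold).
#' @param ref_base Reference base.
#' @param min_reads Minimum independent reads (default 5).
#' @return List with `homozygous_reference` (logical) and `status`: one of
#'   `confirmed`, `genomic_variant`, `insufficient_coverage`, `uncovered`.
#' @export
homozygous_reference <- function(sc, ref_base, min_reads = 5) {
  counts <- c(A = sc$A, C = sc$C, G = sc$G, T = sc$T)
  cov <- sum(counts)
  nonref <- cov - counts[[ref_base]]
  if (cov == 0)
    return(list(homozygous_reference = FALSE, status = "uncovered"))
  if (nonref > 0)
    return(list(homozygous_reference = FALSE, status = "genomic_variant"))
  if (cov < min_reads)
    return(list(homozygous_reference = FALSE,
                status = "insufficient_coverage"))
  list(homozygous_reference = TRUE, status = "confirmed")
}

#' Log-likelihood ratio for editing versus sequencing error
#'
#' Mixture model over the RNA base observations at a site: a read drawn from
#' an edited molecule (probability f) shows the alternative base unless
#' miscalled; one from an unedited molecule shows the reference base. With
#' per-base error `e_i = 10^(-q_i/10)` and uniform miscalls
#' (`P(b | true x) = 1 - e` if `b = x`, else `e/3`), the statistic is
#' `log10( max_f L(f) / L(0) )`, maximized over f in `[0, 1]`.
#'
#' @param obs data.frame of base observations (columns base, phred); bases
#'   other than `ref_base`/`alt_base` are ignored (assumed removed upstream).
#' @param ref_base,alt_base Reference and edited base.
#' @param tol Tolerance of the 1-D likelihood maximization (default 1e-4).
#' @return List of class `llr_result` with `llr` (log10, >= 0) and `f_hat`
#'   (maximum-likelihood editing level; 0 exactly when llr is 0).
#' @export
llr_editing <- function(obs, ref_base, alt_base, tol = 1e-4) {
  obs <- obs[obs$base %in% c(ref_base, alt_base), , drop = FALSE]
  if (nrow(obs) == 0L)
    stop("llr_editing: no usable base observations")
  is_alt <- obs$base == alt_base
  eps <- 10^(-obs$phred / 10)
  # per-read P(b | molecule edited) and P(b | molecule unedited)
  p_alt <- ifelse(is_alt, 1 - eps, eps / 3)
  p_ref <- ifelse(is_alt, eps / 3, 1 - eps)
  loglik <- function(f) sum(log10(f * p_alt + (1 - f) * p_ref))
  ll0 <- loglik(0)
  opt <- stats::optimize(loglik, interval = c(0, 1), maximum = TRUE,
                         tol = tol)
  f_hat <- opt$maximum
  llr <- opt$objective - ll0
  if (llr <= 0 || loglik(0) >= opt$objective) { f_hat <- 0; llr <- 0 }
  structure(list(llr = llr, f_hat = f_hat), class = "llr_result")
}

#' Validate RNA editing candidates against DNA alignments
#'
#' Annotates each candidate with exome evidence: quality-filtered DNA base
#' counts, the homozygous-reference verdict, and -- for homozygous-reference
#' sites with RNA alignments supplied -- the log-likelihood ratio supporting
#' editing over sequencing error computed from the RNA base qualities.
#' Candidate ordering is preserved.
#'
#' @param candidates Candidate data.frame from [call_candidates()].
#' @param dna_aln DNA (exome) alignment data.frame.
#' @param rna_aln Optional RNA alignment data.frame used to gather per-base
#'   observations for the LLR.
#' @param min_dna_quality Minimum DNA base quality (default 30).
#' @param min_dna_reads Minimum DNA reads for the homozygosity call
#'   (default 5).
#' @param min_rna_quality Minimum RNA base quality for LLR observations
#'   (default 25).
#' @return `candidates` with columns cov_dna, dna_A..dna_T, status, llr,
#'   f_hat appended.
#' @export
validate_candidates <- function(candidates, dna_aln, rna_aln = NULL,
                                min_dna_quality = 30, min_dna_reads = 5,
                                min_rna_quality = 25) {
  n <- nrow(candidates)
  candidates$cov_dna <- integer(n)
  candidates$dna_A <- integer(n); candidates$dna_C <- integer(n)
  candidates$dna_G <- integer(n); candidates$dna_T <- integer(n)
  candidates$status <- character(n)
  candidates$llr <- NA_real_
  candidates$f_hat <- NA_real_
  for (i in seq_len(n)) {
    sc <- dna_site_counts(dna_aln, candidates$chrom[i], candidates$pos[i],
                          candidates$ref[i], min_quality = min_dna_quality)
    hz <- homozygous_reference(sc, candidates$ref[i],
                               min_reads = min_dna_reads)
    candidates$cov_dna[i] <- sc$coverage
    candidates$dna_A[i] <- sc$A; candidates$dna_C[i] <- sc$C
    candidates$dna_G[i] <- sc$G; candidates$dna_T[i] <- sc$T
    candidates$status[i] <- hz$status
    if (hz$homozygous_reference && !is.null(rna_aln)) {
      obs <- site_observations(rna_aln, candidates$chrom[i],
                               candidates$pos[i])
      obs <- obs[obs$phred >= min_rna_quality &
                 obs$base %in% c(candidates$ref[i], candidates$alt[i]), ,
                 drop = FALSE]
      if (nrow(obs) > 0L) {
        res <- llr_editing(obs, candidates$ref[i], candidates$alt[i])
        candidates$llr[i] <- res$llr
        candidates$f_hat[i] <- res$f_hat
      }
    }
  }
  candidates
}
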