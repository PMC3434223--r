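#' Configuration for the editing caller
#'
#' Defaults mirror the published strategy: base quality >= 25, site coverage
#' >= 10 reads, editing extent >= 10\%, FDR <= 0.05, coding regions only.
#'
#' @param min_base_quality Minimum Phred base quality used for pileup counts
#'   and the spectrum (default 25; raise to 30 for noisier libraries).
#' @param min_coverage Minimum quality-filtered coverage at a site
#'   (default 10).
#' @param min_editing_fraction Minimum editing extent
#'   alt/(ref + alt) (default 0.10).
#' @param fdr_threshold Benjamini-Hochberg adjusted p-value cutoff
#'   (default 0.05).
#' @param region Region class to test: one of `"cds"`, `"utr5"`, `"utr3"`,
#'   `"alt-exon"`, `"all"` (default `"cds"`).
#' @param stranded Library is strand-oriented; the transcribed strand is then
#'   taken from read orientation rather than the annotation (default FALSE).
#' @param end_trim Number of bases masked at each read end before counting
#'   (default 0; the double-mapping strategy relies on aligner soft
#'   trimming instead).
#' @param background How the Fisher table's second row is built:
#'   `"counts"` (default) uses the spectrum's genome-wide match/substitution
#'   counts for the site's substitution type, minus the site's own counts;
#'   `"expected"` uses rounded expected counts coverage * rate.
#' @return A list of class `caller_config`.
#' @export
caller_config <- function(min_base_quality = 25, min_coverage = 10,
                          min_editing_fraction = 0.10, fdr_threshold = 0.05,
                          region = "cds", stranded = FALSE, end_trim = 0L,
                          background = c("counts", "expected")) {
  background <- match.arg(background)
  region <- match.arg(tolower(region),
                      c("cds", "utr5", "utr3", "alt-exon", "all"))
  stopifnot(min_base_quality >= 0, min_coverage > 0,
            min_editing_fraction >= 0, min_editing_fraction <= 1,
            fdr_threshold > 0, fdr_threshold <= 1, end_trim >= 0)
  structure(list(min_base_quality = min_base_quality,
                 min_coverage = min_coverage,
                 min_editing_fraction = min_editing_fraction,
                 fdr_threshold = fdr_threshold, region = region,
                 stranded = stranded, end_trim = as.integer(end_trim),
                 background = background),
            class = "caller_config")
}

#' Editing extent at a site
#'
#' Fraction of quality-filtered reads carrying the edited base among reads
#' carrying the reference or edited base.
#'
#' @param counts Named or positional numeric vector of filtered base counts
#'   in A, C, G, T order (or a one-row site-count data.frame).
#' @param ref_base,alt_base Reference and edited base (genome orientation).
#' @return Fraction in `[0, 1]`; 0 when no reference or edited base was seen.
#' @export
editing_fraction <- function(counts, ref_base, alt_base) {
  stopifnot(ref_base != alt_base)
  if (is.data.frame(counts))
    counts <- c(A = counts$A, C = counts$C, G = counts$G, T = counts$T)
  if (is.null(names(counts)) || !all(c("A", "C", "G", "T") %in% names(counts)))
    names(counts) <- c("A", "C", "G", "T")
  den <- counts[[ref_base]] + counts[[alt_base]]
  if (den == 0) return(0)
  counts[[alt_base]] / den
}

#' Two-sided Fisher exact test for a 2x2 site-versus-background table
#'
#' Exact p-value for the table `[[site_ref, site_alt], [bg_ref, bg_alt]]`
#' computed by hypergeometric enumeration over all tables with the observed
#' margins; the two-sided p sums the probabilities of every table at most as
#' probable as the observed one.
#'
#' @param site_ref,site_alt Quality-filtered reference/alternative counts at
#'   the tested site.
#' @param bg_ref,bg_alt Background reference/alternative counts.
#' @return p-value in (0, 1].
#' @export
fisher_site_test <- function(site_ref, site_alt, bg_ref, bg_alt) {
  cnt <- c(site_ref, site_alt, bg_ref, bg_alt)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
  if (site_ref + site_alt == 0)
    stop("fisher_site_test: empty site row")
  if (sum(cnt) == 0) stop("fisher_site_test: all-zero table")
  r1 <- site_ref + site_alt
  c1 <- site_ref + bg_ref
  c2 <- site_alt + bg_alt
  support <- seq.int(max(0, r1 - c2), min(r1, c1))
  dens <- stats::dhyper(support, c1, c2, r1)
  d_obs <- stats::dhyper(site_ref, c1, c2, r1)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(max(p, .Machine$double.xmin), 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure: with p-values sorted ascending,
#' `q_i = min over j >= i of m * p_(j) / j`, capped at 1, returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (FDR), same order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  q <- pmin(rev(cummin(rev(m * p[o] / seq_len(m)))), 1)
  # guard the adjusted >= raw invariant against 1-ulp rounding in m*p/j
  pmax(q[order(o)], p)
}

#' Call candidate A-to-I editing sites
#'
#' Applies the full filter cascade to piled-up site counts: SNP masking,
#' genic location with the strand rule (an A>G change on the transcribed
#' strand appears as genome A>G in plus-strand genes and T>C in minus-strand
#' genes), exclusion of sites showing any third base after quality filtering,
#' minimum coverage, minimum editing extent, region class, and a per-site
#' Fisher exact test of the site's ref/alt composition against the
#' spectrum-derived background with Benjamini-Hochberg FDR control. The
#' tested site's own counts are subtracted from the background row. The FDR
#' family is the set of sites surviving all hard filters.
#'
#' @param sites Site counts from [pileup()] built at
#'   `config$min_base_quality`.
#' @param spectrum [build_spectrum()] result at the same quality threshold.
#' @param snps [snp_table()] of known polymorphisms (may be empty).
#' @param models List of gene models.
#' @param config A [caller_config()].
#' @param genome Genome (needed for codon-consequence annotation).
#' @param reference_set Optional reference transcript ids (see
#'   [assign_region()]).
#' @param repeat_intervals Optional repeat intervals (see [assign_region()]).
#' @return data.frame of candidate sites sorted by ascending p-value (ties by
#'   chromosome, position): chrom, pos, gene, transcript_id, strand, region,
#'   ref, alt, st, counts, coverage, editing_fraction, p_value, fdr and codon
#'   consequence columns cc/aac/codp.
#' @export
call_candidates <- function(sites, spectrum, snps, models, config,
                            genome = NULL, reference_set = NULL,
                            repeat_intervals = NULL) {
  stopifnot(inherits(config, "caller_config"))
  minq <- attr(sites, "min_quality")
  if (!is.null(minq) && minq != config$min_base_quality)
    stop("call_candidates: site counts built at Q", minq,
         " but config requires Q", config$min_base_quality)
  if (spectrum$min_quality != config$min_base_quality)
    stop("call_candidates: spectrum built at Q", spectrum$min_quality,
         " but config requires Q", config$min_base_quality)
  empty <- .empty_candidates()
  if (nrow(sites) == 0L) return(empty)

  keep <- !snp_contains(snps, sites$chrom, sites$pos)              # (i)
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)

  rate <- spectrum_frequencies(spectrum)$per_ref_rate
  region_ok <- switch(config$region,
    all = c("CDS", "UTR5", "UTR3", "alt-exon", "intron"),
    cds = "CDS", utr5 = "UTR5", utr3 = "UTR3", `alt-exon` = "alt-exon")

  rows <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    ann <- assign_region(s$chrom, s$pos, models, reference_set,
                         repeat_intervals)
    if (ann$region == "intergenic") next                           # (ii)
    strand <- ann$strand
    if (config$stranded && (s$n_plus + s$n_minus) > 0) {
      read_strand <- if (s$n_plus >= s$n_minus) "+" else "-"
      if (!identical(read_strand, strand)) next
    }
    ref <- if (strand == "+") "A" else "T"
    alt <- if (strand == "+") "G" else "C"
    if (s$ref != ref) next                                         # (ii)
    others <- setdiff(c("A", "C", "G", "T"), c(ref, alt))
    if (s[[others[1]]] + s[[others[2]]] > 0) next                  # (iii)
    if (s$coverage < config$min_coverage) next                     # (iv)
    ef <- editing_fraction(s, ref, alt)
    if (ef < config$min_editing_fraction || s[[alt]] == 0) next    # (v)
    if (!ann$region %in% region_ok) next                           # (vii)
    type <- paste0(ref, ">", alt)
    if (config$background == "counts") {
      bg_ref <- max(spectrum$match_counts[[ref]] - s[[ref]], 0)
      bg_alt <- max(spectrum$sub_counts[[type]] - s[[alt]], 0)
    } else {
      bg_alt <- round(s$coverage * rate[[type]])
      bg_ref <- s$coverage - bg_alt
    }
    p <- fisher_site_test(s[[ref]], s[[alt]], bg_ref, bg_alt)      # (vi)
    rows[[i]] <- data.frame(
      chrom = s$chrom, pos = s$pos, gene = ann$gene,
      transcript_id = ann$transcript_id, strand = strand,
      region = ann$region, ref = ref, alt = alt,
      st = paste0(ref, alt),
      raw_A = s$raw_A, raw_C = s$raw_C, raw_G = s$raw_G, raw_T = s$raw_T,
      A = s$A, C = s$C, G = s$G, T = s$T, coverage = s$coverage,
      editing_fraction = ef, p_value = p,
      repeat_overlap = ann$repeat_overlap,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out <- out[out$fdr <= config$fdr_threshold, , drop = FALSE]
  if (nrow(out) == 0L) return(empty)

  # codon consequence for CDS candidates
  out$cc <- NA_character_; out$aac <- NA_character_
  out$codp <- NA_integer_
  if (!is.null(genome)) {
    names(models) <- vapply(models, `[[`, character(1), "transcript_id")
    for (i in seq_len(nrow(out))) {
      if (out$region[i] != "CDS") next
      m <- models[[out$transcript_id[i]]]
      eff <- codon_effect(out$chrom[i], out$pos[i], m, genome,
                          alt_base = out$alt[i])
      out$cc[i] <- paste0(eff$ref_codon, "->", eff$alt_codon)
      out$aac[i] <- paste0(eff$ref_aa, "->", eff$alt_aa)
      out$codp[i] <- eff$codon_position
    }
  }
  out <- out[order(out$p_value, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_candidates <- function() {
  data.frame(chrom = character(0), pos = integer(0), gene = character(0),
             transcript_id = character(0), strand = character(0),
             region = character(0), ref = character(0), alt = character(0),
             st = character(0), raw_A = integer(0), raw_C = integer(0),
             raw_G = integer(0), raw_T = integer(0), A = integer(0),
             C = integer(0), G = integer(0), T = integer(0),
             coverage = integer(0), editing_fraction = numeric(0),
             p_value = numeric(0), repeat_overlap = logical(0),
             fdr = numeric(0), cc = character(0), aac = character(0),
             codp = integer(0), stringsAsFactors = FALSE)
}

#' Mask read ends before counting
#'
#' Reproduces end-trimming strategies by setting the Phred quality of the
#' first and last `n` bases of every read to 0, so they fail any positive
#' base-quality filter while leaving the alignment geometry intact.
#'
#' @param aln Alignment data.frame.
#' @param n Bases to mask at each end.
#' @return The alignment data.frame with masked qualities.
#' @export
trim_read_ends <- function(aln, n) {
  n <- as.integer(n)
  if (n <= 0L || nrow(aln) == 0L) return(aln)
  aln$qual <- vapply(aln$qual, function(q) {
    L <- nchar(q)
    k <- min(n, L)
    q <- `substring<-`(q, 1L, k, strrep("!", k))
    if (L > n) q <- `substring<-`(q, L - k + 1L, L, strrep("!", k))
    q
  }, character(1), USE.NAMES = FALSE)
  aln
}
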