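#' Tally base observations at a single site
#'
#' Raw counts tally every non-N, non-duplicate base; filtered counts keep
#' only bases with Phred quality at least `min_quality`. N bases count in
#' neither.
#'
#' @param obs data.frame of base observations with columns `base` and `phred`
#'   (optionally `duplicate`).
#' @param ref_base Reference base at the site.
#' @param min_quality Minimum Phred quality for the filtered counts
#'   (default 25).
#' @return One-row data.frame with ref, raw_A..raw_T, A..T and coverage (sum
#'   of filtered counts).
#' @export
pileup_site_counts <- function(obs, ref_base, min_quality = 25) {
  if (!is.null(obs$duplicate)) obs <- obs[!obs$duplicate, , drop = FALSE]
  obs <- obs[obs$base %in% c("A", "C", "G", "T"), , drop = FALSE]
  tab <- function(b) c(A = sum(b == "A"), C = sum(b == "C"),
                       G = sum(b == "G"), T = sum(b == "T"))
  raw <- tab(obs$base)
  flt <- tab(obs$base[obs$phred >= min_quality])
  data.frame(ref = ref_base,
             raw_A = raw[["A"]], raw_C = raw[["C"]], raw_G = raw[["G"]],
             raw_T = raw[["T"]],
             A = flt[["A"]], C = flt[["C"]], G = flt[["G"]], T = flt[["T"]],
             coverage = sum(flt), stringsAsFactors = FALSE)
}

#' Pileup base counts over all covered sites
#'
#' Expands aligned blocks of every record into per-position base
#' observations (duplicate-flagged records excluded, N bases ignored) and
#' tallies, per genomic site, raw counts and counts passing the base-quality
#' filter. Also counts, among quality-passing bases, observations from plus-
#' and minus-strand fragments (mate-2 orientation is flipped), which supports
#' strand-aware calling on stranded libraries.
#'
#' @param aln Alignment data.frame (from [read_sam()] or the simulator).
#' @param genome Genome from [read_genome()].
#' @param min_quality Minimum Phred base quality (default 25).
#' @param exclude_duplicates Drop duplicate-flagged records (default TRUE).
#' @return data.frame of site counts: chrom, pos, ref, raw_A..raw_T, A..T,
#'   coverage, n_plus, n_minus; sorted by chrom then pos, with the quality
#'   threshold in the `min_quality` attribute.
#' @export
pileup <- function(aln, genome, min_quality = 25, exclude_duplicates = TRUE) {
  if (exclude_duplicates && !is.null(aln$duplicate))
    aln <- aln[!aln$duplicate, , drop = FALSE]
  if (!is.null(aln$unmapped)) aln <- aln[!aln$unmapped, , drop = FALSE]
  if (nrow(aln) == 0L) return(.empty_sites(min_quality))
  ops <- c("M", "=", "X")
  rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    aln$cigar, pos = aln$pos, ops = ops)
  qr <- GenomicAlignments::cigarRangesAlongQuerySpace(aln$cigar, ops = ops)
  w <- unlist(IRanges::width(rr), use.names = FALSE)
  rstart <- unlist(IRanges::start(rr), use.names = FALSE)
  qstart <- unlist(IRanges::start(qr), use.names = FALSE)
  blk_read <- rep(seq_len(nrow(aln)), S4Vectors::elementNROWS(rr))
  gpos <- sequence(w, from = rstart)
  qoff <- sequence(w, from = qstart)
  ridx <- rep(blk_read, w)
  offsets <- cumsum(nchar(aln$seq)) - nchar(aln$seq)
  abs_idx <- offsets[ridx] + qoff
  chars <- unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE)
  qint <- utf8ToInt(paste(aln$qual, collapse = "")) - 33L
  frag_minus <- xor(aln$strand == "-", aln$mate2)
  dt <- data.table::data.table(
    chrom = aln$rname[ridx], pos = gpos, base = chars[abs_idx],
    q = qint[abs_idx], minus = frag_minus[ridx])
  dt <- dt[dt$base != "N"]
  if (nrow(dt) == 0L) return(.empty_sites(min_quality))
  .N <- base <- q <- minus <- NULL  # data.table NSE
  raw <- data.table::dcast(dt[, .N, by = c("chrom", "pos", "base")],
                           chrom + pos ~ base, value.var = "N", fill = 0L)
  fdt <- dt[q >= min_quality]
  flt <- data.table::dcast(fdt[, .N, by = c("chrom", "pos", "base")],
                           chrom + pos ~ base, value.var = "N", fill = 0L)
  strd <- fdt[, list(n_plus = sum(!minus), n_minus = sum(minus)),
              by = c("chrom", "pos")]
  for (b in c("A", "C", "G", "T")) {
    if (is.null(raw[[b]])) raw[[b]] <- 0L
    if (is.null(flt[[b]])) flt[[b]] <- 0L
  }
  out <- merge(raw[, c("chrom", "pos", "A", "C", "G", "T"), with = FALSE],
               flt[, c("chrom", "pos", "A", "C", "G", "T"), with = FALSE],
               by = c("chrom", "pos"), all.x = TRUE,
               suffixes = c(".raw", ""))
  out <- merge(out, strd, by = c("chrom", "pos"), all.x = TRUE)
  for (b in c("A", "C", "G", "T")) out[[b]][is.na(out[[b]])] <- 0L
  out$n_plus[is.na(out$n_plus)] <- 0L
  out$n_minus[is.na(out$n_minus)] <- 0L
  data.table::setnames(out, paste0(c("A", "C", "G", "T"), ".raw"),
                       paste0("raw_", c("A", "C", "G", "T")))
  out <- as.data.frame(out)
  out$ref <- genome_base(genome, out$chrom, out$pos)
  out$coverage <- out$A + out$C + out$G + out$T
  out <- out[order(out$chrom, out$pos),
             c("chrom", "pos", "ref", "raw_A", "raw_C", "raw_G", "raw_T",
               "A", "C", "G", "T", "coverage", "n_plus", "n_minus")]
  rownames(out) <- NULL
  attr(out, "min_quality") <- min_quality
  out
}

.empty_sites <- function(min_quality) {
  out <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                    raw_A = integer(0), raw_C = integer(0), raw_G = integer(0),
                    raw_T = integer(0), A = integer(0), C = integer(0),
                    G = integer(0), T = integer(0), coverage = integer(0),
                    n_plus = integer(0), n_minus = integer(0),
                    stringsAsFactors = FALSE)
  attr(out, "min_quality") <- min_quality
  out
}

#' Base observations at one genomic site
#'
#' Returns the individual aligned bases covering a position, with their Phred
#' qualities, fragment strand, read id and duplicate flag -- the raw material
#' for the log-likelihood ratio statistic.
#'
#' @param aln Alignment data.frame.
#' @param chrom,pos Site coordinates (1-based).
#' @param exclude_duplicates Drop duplicate-flagged records (default TRUE).
#' @return data.frame with columns read_id, base, phred, strand, duplicate.
#' @export
site_observations <- function(aln, chrom, pos, exclude_duplicates = TRUE) {
  aln <- aln[aln$rname == chrom & !aln$unmapped & aln$pos <= pos, ,
             drop = FALSE]
  if (exclude_duplicates) aln <- aln[!aln$duplicate, , drop = FALSE]
  empty <- data.frame(read_id = character(0), base = character(0),
                      phred = integer(0), strand = character(0),
                      duplicate = logical(0), stringsAsFactors = FALSE)
  if (nrow(aln) == 0L) return(empty)
  ref_w <- GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar)
  aln <- aln[aln$pos + ref_w - 1L >= pos, , drop = FALSE]
  if (nrow(aln) == 0L) return(empty)
  rows <- lapply(seq_len(nrow(aln)), function(i) {
    rr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      aln$cigar[i], pos = aln$pos[i], ops = c("M", "=", "X"))[[1]]
    qr <- GenomicAlignments::cigarRangesAlongQuerySpace(
      aln$cigar[i], ops = c("M", "=", "X"))[[1]]
    hit <- which(pos >= IRanges::start(rr) & pos <= IRanges::end(rr))
    if (length(hit) == 0L) return(NULL)
    qidx <- IRanges::start(qr)[hit] + (pos - IRanges::start(rr)[hit])
    data.frame(read_id = aln$qname[i],
               base = substring(aln$seq[i], qidx, qidx),
               phred = utf8ToInt(substring(aln$qual[i], qidx, qidx)) - 33L,
               strand = aln$strand[i], duplicate = aln$duplicate[i],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

# ---- substitution spectrum --------------------------------------------------

.SUB_TYPES <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              function(x, y) paste0(x, ">", y)))
.SUB_TYPES <- .SUB_TYPES[substr(.SUB_TYPES, 1, 1) != substr(.SUB_TYPES, 3, 3)]

#' The 12 reference-to-observed substitution types
#' @return Character vector like `"A>G"`, in reference-genome orientation.
#' @export
substitution_types <- function() .SUB_TYPES

#' Build the empirical substitution spectrum
#'
#' Sums quality-filtered base counts over all piled-up sites not listed in
#' the SNP table: reference-matching bases into `match_counts[ref]` and each
#' mismatch base into `sub_counts[ref>obs]`. The relative frequency of each
#' substitution type over the global substitution total is the empirical
#' background used by the editing caller. Known polymorphisms are masked
#' because they are genuine genomic variation, not sequencing noise, and
#' would inflate the A>G background.
#'
#' @param sites Site counts from [pileup()] (single quality threshold).
#' @param snps Optional [snp_table()] of positions to mask.
#' @param restrict_to Optional list of gene models; when given, only sites
#'   exonic in at least one model contribute (by default every covered site
#'   does).
#' @return An object of class `substitution_spectrum`: `sub_counts` (named
#'   12-vector), `match_counts` (named 4-vector), `min_quality`,
#'   `masked_sites`.
#' @export
build_spectrum <- function(sites, snps = NULL, restrict_to = NULL) {
  minq <- attr(sites, "min_quality")
  if (is.null(minq))
    stop("build_spectrum: site counts carry no min_quality attribute")
  masked <- 0L
  if (!is.null(snps) && nrow(sites) > 0L) {
    m <- snp_contains(snps, sites$chrom, sites$pos)
    masked <- sum(m)
    sites <- sites[!m, , drop = FALSE]
  }
  if (!is.null(restrict_to) && nrow(sites) > 0L) {
    keep <- rep(FALSE, nrow(sites))
    for (m in restrict_to) {
      sel <- sites$chrom == m$chrom
      if (!any(sel)) next
      ex <- rep(FALSE, sum(sel))
      for (i in seq_along(m$exon_start))
        ex <- ex | (sites$pos[sel] >= m$exon_start[i] &
                    sites$pos[sel] <= m$exon_end[i])
      keep[sel] <- keep[sel] | ex
    }
    sites <- sites[keep, , drop = FALSE]
  }
  sub_counts <- stats::setNames(numeric(length(.SUB_TYPES)), .SUB_TYPES)
  match_counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (r in c("A", "C", "G", "T")) {
    sel <- sites$ref == r
    if (!any(sel)) next
    for (b in c("A", "C", "G", "T")) {
      tot <- sum(sites[[b]][sel])
      if (b == r) match_counts[[r]] <- match_counts[[r]] + tot
      else sub_counts[[paste0(r, ">", b)]] <-
             sub_counts[[paste0(r, ">", b)]] + tot
    }
  }
  structure(list(sub_counts = sub_counts, match_counts = match_counts,
                 min_quality = minq, masked_sites = masked),
            class = "substitution_spectrum")
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat("<substitution_spectrum> Q>=", x$min_quality, ", ",
      sum(x$sub_counts), " substitutions / ", sum(x$match_counts),
      " matches, ", x$masked_sites, " SNP sites masked\n", sep = "")
  nz <- x$sub_counts[x$sub_counts > 0]
  if (length(nz)) print(nz)
  invisible(x)
}

#' Substitution-type frequencies and per-reference rates
#'
#' `type_freq[X>Y]` is the share of substitution type X>Y among all observed
#' substitutions (sums to 1 when any substitution was seen). `per_ref_rate`
#' is the mismatch rate per opportunity:
#' `sub_counts[X>Y] / (match_counts[X] + sum_Z sub_counts[X>Z])`.
#'
#' @param spectrum A `substitution_spectrum`.
#' @return List with numeric 12-vectors `type_freq` and `per_ref_rate` (zero
#'   where the denominator is zero).
#' @export
spectrum_frequencies <- function(spectrum) {
  tot <- sum(spectrum$sub_counts)
  type_freq <- if (tot > 0) spectrum$sub_counts / tot
               else spectrum$sub_counts * 0
  per_ref_rate <- spectrum$sub_counts * 0
  for (r in c("A", "C", "G", "T")) {
    types <- grep(paste0("^", r, ">"), .SUB_TYPES, value = TRUE)
    den <- spectrum$match_counts[[r]] + sum(spectrum$sub_counts[types])
    if (den > 0) per_ref_rate[types] <- spectrum$sub_counts[types] / den
  }
  list(type_freq = type_freq, per_ref_rate = per_ref_rate)
}

#' Serialize a spectrum to a two-column TSV
#' @param spectrum A `substitution_spectrum`.
#' @param path Output file; the quality threshold and masked-site count are
#'   recorded in '#' header lines.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# min_quality=%d", as.integer(spectrum$min_quality)),
               sprintf("# masked_sites=%d", as.integer(spectrum$masked_sites)),
               "type\tcount"), con)
  writeLines(c(sprintf("%s\t%.0f", names(spectrum$sub_counts),
                       spectrum$sub_counts),
               sprintf("match_%s\t%.0f", names(spectrum$match_counts),
                       spectrum$match_counts)), con)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#' @param path Spectrum TSV file.
#' @return A `substitution_spectrum`.
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  minq <- as.integer(sub("# min_quality=", "",
                         grep("^# min_quality=", lines, value = TRUE)[1]))
  masked <- as.integer(sub("# masked_sites=", "",
                           grep("^# masked_sites=", lines, value = TRUE)[1]))
  body <- lines[!grepl("^#", lines)][-1L]
  parts <- strsplit(body, "\t")
  key <- vapply(parts, `[`, character(1), 1L)
  val <- as.numeric(vapply(parts, `[`, character(1), 2L))
  sub_counts <- stats::setNames(numeric(length(.SUB_TYPES)), .SUB_TYPES)
  match_counts <- c(A = 0, C = 0, G = 0, T = 0)
  is_match <- grepl("^match_", key)
  sub_counts[key[!is_match]] <- val[!is_match]
  match_counts[sub("^match_", "", key[is_match])] <- val[is_match]
  structure(list(sub_counts = sub_counts, match_counts = match_counts,
                 min_quality = minq, masked_sites = masked),
            class = "substitution_spectrum")
}
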