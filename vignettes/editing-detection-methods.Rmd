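---
title: "Detecting A-to-I RNA editing without matched genomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting A-to-I RNA editing without matched genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editcall)
```

## The model

A-to-I editing deaminates adenosine in double-stranded RNA; inosine pairs
like guanosine, so in an RNA-Seq pileup an edited site shows a mixture of A
and G reads (T and C in genome orientation under a minus-strand gene).
Because edited and unedited transcripts coexist in the same cell, the editing
extent — the fraction of reads carrying G among reads carrying A or G — can
take any value in (0, 1], which rules out genotype-style diploid callers.

The statistical question editcall answers per site is: *is the observed A/G
composition explicable as ordinary mismatch noise for this dataset?* The
null is empirical, not parametric. Over all covered, non-SNP sites at a fixed
base-quality cutoff, we tally the 12 substitution types X>Y and the four
reference-matching counts. For a site with quality-filtered counts
(n_ref, n_alt) we form the 2×2 table against the dataset-wide background for
the same substitution type — match count M_X minus the site's own reference
count in one cell, substitution count S_X>Y minus the site's own alternative
count in the other — and compute a two-sided Fisher exact test by
hypergeometric enumeration. Benjamini–Hochberg step-up adjustment is applied
across all sites that survive the hard filters, and candidates are reported
at FDR ≤ 0.05, ranked by ascending p-value.

Two design points deserve justification:

* **Two-sample form of the contingency table.** The alternative — comparing
  observed counts with *rounded expected* counts n·p̂ — collapses to an
  all-zero expectation whenever n·p̂ < 0.5, which is the typical situation
  (p̂ ≈ 10⁻³, n ≈ 10–500). The two-sample proportion form is a well-defined
  exact test at any scale and converges to the same comparison for large
  backgrounds. The rounded-expectation variant remains available via
  `caller_config(background = "expected")` for comparison.
* **Self-exclusion.** The tested site's own counts are subtracted from the
  background row. For genome-scale backgrounds the effect is negligible, but
  for the small simulated datasets used in testing it prevents a strongly
  edited site from inflating its own null.

## Filters and their parameters

| parameter | default | units | why |
|---|---|---|---|
| `min_base_quality` | 25 | Phred | mismatches below Q25 are dominated by miscalls; raise to 30 for noisier libraries |
| `min_coverage` | 10 | reads | below ~10 reads the 10% extent threshold cannot be measured meaningfully |
| `min_editing_fraction` | 0.10 | fraction | mitigates residual sequencing error; also the detection floor reported by the method |
| `fdr_threshold` | 0.05 | — | conventional BH level |
| `region` | `"cds"` | — | coding positions have the best annotation support; `utr5`/`utr3`/`alt-exon`/`all` widen the search |
| `stranded` | FALSE | — | with strand-oriented libraries the transcribed strand is taken from read orientation and must agree with the annotation |
| `end_trim` | 0 | bases | masks read ends (quality set to 0) to suppress end-of-read artifacts; off by default because the double-mapping strategy relies on aligner soft-trimming |
| DNA: `min_dna_quality` | 30 | Phred | SNP exclusion needs higher per-base confidence than detection |
| DNA: `min_dna_reads` | 5 | reads | fewer than 5 clean reads cannot distinguish hom-ref from het |

Three further rules are fixed rather than tunable: sites listed in the SNP
table never enter the spectrum or the candidate list (a true polymorphism is
genomic variation, not sequencing noise, and would specifically inflate the
A>G background); duplicate-flagged reads and N bases never contribute to any
count; and a site is only tested when the genome base is A under a
plus-strand gene or T under a minus-strand gene.

## Coordinate projection and the concordance filter

Transcriptome-space alignments are projected to genome coordinates with a
per-base map: transcript position k is the k-th exonic base in genomic order
(plus strand) or the k-th counting down from the highest genomic coordinate
(minus strand); blocks split at exon boundaries and minus-strand reads are
reverse-complemented into genome orientation. A genome-space record is kept
only if the same read (and mate) was uniquely placed in both spaces with
*identical* chromosome, strand and block set; for pairs, both mates must be
concordant. Exact equality rather than overlap tolerance is deliberate: the
filter exists to remove paralog-induced misplacements, and a tolerant
comparison would readmit exactly those. The package does not re-align or
rescue discordant reads, and does not predict splice sites — junctions come
from the gene models.

## Region assignment and codon consequences

A candidate inside the CDS of a reference transcript is `CDS`; exonic but
outside the CDS is `UTR5`/`UTR3` by strand; exonic only in transcripts
outside the designated reference set is `alt-exon`; inside a gene span but
not exonic is `intron`. When transcripts disagree, CDS wins and the
reporting transcript is the one with the longest spliced CDS — annotations
do not state which transcript a published consequence refers to, so a single
deterministic convention is declared rather than inferred. Codon effects
substitute the edited base at its position within the spliced CDS
(strand-aware) and translate with the standard genetic code.

One relaxation against the strictest reading of the interfaces: the
`gene_model` constructor accepts a CDS whose spliced length is not a
multiple of 3 (real annotation files contain such transcripts, and a BED12
thick interval spanning the whole feature is a common way of writing "all
coding"); `codon_effect()` refuses to translate through such a model rather
than guessing a frame.

## The LLR validation statistic

For candidates whose exome evidence is homozygous reference, the per-site
log-likelihood ratio compares a two-component mixture (each RNA molecule is
edited with probability f, then sequenced with per-base error
ε_i = 10^(−q_i/10), miscalls uniform over the three wrong bases, i.e.
P(b|x,ε) = 1−ε if b = x else ε/3) against the pure-error model f = 0. The
likelihood is maximized over f ∈ [0, 1] with Brent's method
(`stats::optimize`, tolerance 1e-4), which is deterministic and embeds
golden-section search; tests pin it to a 1e-5 grid scan. The ratio is
reported in log10 — the published values cannot disambiguate the log base
because they depend on unpublished per-base qualities, and log10 matches the
p-value scale reported alongside. LLR is clamped so that llr = 0 exactly
when f̂ = 0.

## What the simulator emulates — and what it does not

`make_reference` builds one random chromosome with non-overlapping
multi-exon genes on alternating strands, each with 5'UTR/CDS/3'UTR structure
and CDS length divisible by 3. `plant_sites` places editing only at
transcribed-strand adenosines (inside the CDS by default) and SNPs at other
exonic positions. `simulate_reads` draws fragments uniformly from each
transcript; each fragment independently carries the edited base with
probability equal to the site's level — emulating the co-expression of
edited and unedited molecules — carries het SNP alleles at 50% and hom-alt
at 100%, and is sequenced with constant-Phred errors (default Q30,
ε = 10⁻³, uniform wrong base). Fragment length is 180 ± 30 bp, a realistic
short-insert library scale that fits the simulated 750–900 base transcripts;
read length defaults to 50 (2×50 bp libraries). Reads are emitted
*truth-placed* as genome-space spliced alignments, deliberately bypassing
real aligners so that tests isolate the caller's statistics from aligner
behavior; `write_fastq` exists for external-aligner integration.
`add_decoy_paralog`/`misalign_to_paralog` emulate the paralog failure mode:
a diverged copy of one gene attracts a fraction of its genome-space
alignments, which the concordance filter must remove.

Not emulated: indels and splice-mapping errors, quality drift along the
read, position-within-read error profiles, coverage bias beyond the
fragment-edge effect, and real SNP linkage. A green end-to-end test
therefore establishes that the statistics and filters behave as specified
under calibrated noise — not that any particular aligner's output is clean.

## Numerical and degenerate-input choices

* Fisher p-values sum hypergeometric probabilities over the table support
  with a 1+1e-7 slack on "as extreme as observed", the standard guard
  against ties lost to floating point; the result is clamped into
  (0, 1]. An all-zero site row is a contract error, not p = 1.
* `bh_adjust` is the textbook step-up with an explicit `pmax(q, p)` guard:
  m·p/j can land one ulp below p at j = m, and the adjusted-≥-raw invariant
  is part of the contract.
* Empty inputs return empty outputs of the right shape everywhere except
  where the contract demands an error (`llr_editing` on no observations,
  Fisher on an empty site row).
* Coordinates are 1-based inclusive at every user-visible surface; the only
  0-based half-open handling is inside the BED12 reader/writer.
* Chromosome names match by exact string equality; no "chr" aliasing.
* Ties in the candidate ranking are broken by (chromosome, position).
* `bh_adjust`'s FDR family is the set of sites surviving the hard filters
  (SNP mask, gene/strand rule, single substitution type, coverage, extent,
  region) — significance is adjusted after filtering, and the 10% extent
  threshold is applied before correction since it defines the tested family.
  Both points are configurable only by changing the filters themselves.

## Known limitations

* Without DNA evidence, an unlisted SNP at an exonic A with ~50% or ~100%
  alternative fraction is indistinguishable from editing; the SNP table is
  the only genomic defense, which is the price of requiring RNA only.
* The spectrum is genome-orientation and dataset-global; it is not stratified
  by sequence context, read position or strand, so locally clustered error
  modes can leak through the 10% threshold at very high coverage.
* The Fisher background uses every covered site by default (an option
  restricts accumulation to annotated territory); in tiny simulated genomes
  the planted editing itself inflates the A>G background, making the test
  slightly conservative — visible but harmless in the test suite.
* p-values from different datasets are not comparable: the null is the
  dataset's own noise.
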