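Package: editcall
Title: De Novo Detection of A-to-I RNA Editing Sites from RNA-Seq Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate A-to-I RNA editing sites from RNA-Seq
    alignments without genomic reads from the same individual. Implements a
    double-mapping concordance filter (transcriptome-space alignments
    projected to genome coordinates and compared with direct genome
    alignments), quality-filtered pileup base counting, an empirical
    substitution spectrum used as the statistical background, a per-site
    Fisher exact test with Benjamini-Hochberg false discovery rate control
    and hard coverage/extent filters, gene-region and codon-consequence
    annotation, and optional validation against exome alignments via a
    homozygosity rule and a log-likelihood ratio statistic. A simulator
    generates spliced transcripts, stranded paired reads with
    Phred-calibrated errors, planted editing sites and SNPs for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
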