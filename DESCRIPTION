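Package: embryoTE
Title: Transposable-Element Misregulation Analysis in Sexed Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying transposable-element (TE) misregulation on
    repeat-rich Y chromosomes during early embryogenesis. Implements TE and
    gene expression quantification with autosomal-median and copy-number
    normalization, classification of Y-enriched TE families from sexed
    DNA-seq, spike-in quantile-normalized H3K9me3 window enrichment,
    TSS and TE meta-profiles and gene-TE interval analyses, a conservative
    dual-junction caller for de novo TE insertions from discordant
    paired-end reads, and downstream count models (coverage-adjusted ANOVA,
    residual sex comparisons, chromosomal-distribution tests). A synthetic
    data generator with recorded ground truth makes every stage testable
    without external sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
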