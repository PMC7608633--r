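# embryoTE

Tools for studying transposable-element (TE) misregulation on repeat-rich
Y chromosomes during early embryogenesis, built for sexed single-embryo
sequencing designs (RNA-seq, DNA-seq, and spike-in H3K9me3 ChIP-seq
across developmental stages).

Young, repeat-dense Y chromosomes that still carry actively transcribed
genes are hard to silence: heterochromatin formation and genic
transcription compete, TEs near active Y genes escape repression, and
male embryos accumulate elevated TE expression — and ultimately more de
novo TE insertions — relative to females. `embryoTE` implements the
computational machinery needed to quantify each link of that chain, plus
a synthetic-data generator with recorded ground truth so every stage is
testable without external sequencing data.

## What the package computes

**Repeat expression quantification** (`count_features`,
`normalize_autosomal_median`, `copy_number_normalize`,
`sex_fold_difference`, `correlation_cluster`, `compare_sexes_wilcoxon`,
`classify_y_enriched`). Counts per gene / TE family are normalized per
library by the **median count over autosomal genes** (robust to
sex-chromosome expression), a pseudocount is added, and analyses run on
log2 values. TE expression can additionally be divided by sex-matched
DNA-seq abundance to remove copy-number effects. A TE family is
**Y-enriched** when its DNA-seq abundance in males is ≥ 2× that in
females.

**Spike-in ChIP normalization** (`split_spike_reads`,
`window_enrichment`, `build_spike_reference`,
`spikein_quantile_normalize`). Enrichment in 50-kb windows is

```
(ChIP reads / median autosomal coverage of ChIP library)
---------------------------------------------------------
(input reads / median autosomal coverage of input library)
```

Every library shares the same foreign spike-in chromatin, so each
library's spike enrichment distribution is quantile-matched to the
cross-library reference, and the resulting value→value correction map is
applied to the library's own genome — removing antibody
pulldown-efficiency differences. If spike windows at enrichment 1.5 are
corrected to 2, sample windows at 1.5 become 2.

**Interval analyses** (`window_gene_classes`, `metaprofile`,
`gene_te_distances`, `insertions_near_genes`,
`regress_family_counts_vs_expression`): H3K9me3 in windows overlapping
genes / zygotically expressed genes, median per-bp profiles ±5 kb around
TSSs or TE midpoints, gene–TE nearest distances, and per-family counts
of insertions within ±5 kb of zygotic genes regressed on expression.

**De novo TE insertion caller** (`find_junction_pairs`,
`cluster_junctions`, `call_insertions`, `filter_novel`,
`exon_control`). From paired-end reads mapped single-end to a
repeat-masked genome and a TE consensus library, it keeps pairs with one
uniquely mapped genomic read and a TE-only mate, chains same-orientation
reads within 100 bp into junctions, and calls an insertion only when a
forward (5′) junction is followed by a reverse (3′) junction < 100 bp
downstream — the dual-junction rule that rejects single-junction
chimeric artifacts. Calls within < 50 bp of a call in another sample are
discarded (mutually) so only embryo-private, de novo events remain. The
same pipeline run with exon sequences instead of repeats
(`exon_control`) measures the false-positive floor.

**Insertion-count statistics** (`fit_anova`, `coverage_residuals`,
`chromosome_distribution_test`): sequential ANOVA of
`insertions ~ coverage + sex + stage`, coverage-adjusted residual
comparisons between sexes per stage, and per-chromosome observed vs
expected counts under a uniform insertion rate proportional to the
sex-specific diploid chromosome sizes.

**Synthetic data** (`make_genome`, `plant_insertions`,
`simulate_dna_reads`, `simulate_rna_counts`, `simulate_chip_reads`,
`simulate_dna_counts`): a small multi-chromosome genome with a
repeat-dense gene-bearing Y, planted germline TE copies and de novo
insertions at controlled cell fractions, stage×sex RNA counts with a
maternal-to-zygotic transition, and ChIP/input reads with spike-in and
pulldown distortion — all with serialized truth.

## Worked example

Plant five fully clonal insertions, sequence the embryo at 30×, and call
them back:

```r
library(embryoTE)

genome <- make_genome(synth_genome_spec(seed = 11))
genome
#> Synthetic genome: 4 chromosomes, 2800000 bp; 20 TE families;
#>   144 planted copies; 141 genes

genome <- plant_insertions(genome, n = 5, samples = "embryo1",
                           cell_fraction = 1, seed = 12)
reads <- simulate_dna_reads(genome, "embryo1", depth = 30, seed = 13)
reads
#> Read set for embryo1 : 420000 pairs; 793828 genome-aligned,
#>   38709 TE-aligned, 8803 unaligned reads

calls <- call_te_insertions(reads)
calls[, c("chrom", "pos5", "pos3", "family", "support5", "support3")]
#>   chrom   pos5   pos3 family support5 support3
#> 1  chr2 265640 265651  TE007       42       47
#> 4  chr2 514083 514093  TE016       40       49
#> 3  chr2 653599 653601  TE012       46       61
#> 2  chr2 659575 659592  TE010       42       48
#> 5  chr3 556274 556280  TE013       37       47

genome$truth$insertions[, c("chrom", "pos", "family")]
#>   chrom    pos family
#> 1  chr2 653599  TE012
#> 2  chr2 659581  TE010
#> 3  chr2 265643  TE007
#> 4  chr2 514090  TE016
#> 5  chr3 556277  TE013
```

All five planted insertions are recovered, each bracketed by its 5′ and
3′ junction within a few bp of the true insertion point, with ~40 reads
of support per junction and no false calls.

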