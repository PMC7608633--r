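---
title: "Methods and design of the embryoTE pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the embryoTE pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

During early embryogenesis the zygotic genome starts out epigenetically
naive: transcription is driven by maternally deposited products, and
repressive heterochromatin (marked by H3K9me3) is only established
around the maternal-to-zygotic (MZ) transition. Repeat-rich Y
chromosomes are a worst case for this process — and a *young* Y that
still carries many actively transcribed genes is worse still, because
transcription locally antagonizes heterochromatin formation. The
downstream prediction is concrete and measurable: male embryos should
show elevated TE expression after the MZ transition, driven by Y-linked
TE families, with reduced H3K9me3 near active Y genes, and an excess of
de novo TE insertions.

`embryoTE` implements the quantitative machinery for each of those
measurements. This vignette documents the models, the parameter choices,
the synthetic-data generator, and the numerical decisions — including
where the design was genuinely open and what we chose.

# Expression quantification and normalization

**Autosomal-median normalization.** Each library's feature counts are
divided by that library's median count over autosomal genes. Unlike
total-count scaling, this normalizer is insensitive to how much of the
library derives from sex chromosomes — essential when a gene-rich neo-Y
contributes a large, male-specific slice of the transcriptome. A
pseudocount (default 1) is then added so that log2 transforms are
defined. We add it to every feature, genes and TEs alike, because TE
values are also log-transformed downstream; a flag restricts it to genes
only. The normalizer requires a positive median: a library whose median
autosomal gene count is zero is an error, not a silent NaN.

One practical consequence worth knowing: the stability of every
downstream fold estimate is bounded by the stability of this median.
With only a few dozen autosomal genes the normalizer itself fluctuates
by several percent and shifts all of a library's values coherently; with
the thousands of genes of a real annotation it is essentially exact. Our
simulations therefore use ~2000 autosomal genes when fold recovery is
being measured.

**Copy-number normalization.** Male/female expression ratios at TEs
conflate regulation with dosage (males carry the Y's extra copies).
Dividing each TE's normalized RNA value by its normalized DNA-seq value
in sex-matched DNA libraries cancels dosage: if RNA and DNA folds are
equal, the corrected fold is exactly 1. The DNA normalizer per RNA
sample is the mean over DNA libraries of the same sex (an override hook
accepts any matcher). A DNA value of zero makes the corrected value
undefined; we emit `NA`, never 0.

**Sex folds, clustering, tests.** Per-feature fold differences are
log2(mean over male replicates / mean over female replicates) at a
stage, on pseudocounted values; replicate aggregation is the arithmetic
mean. Sample correlation and clustering run on log2 values with Pearson
correlation and complete linkage on `1 - r` (the linkage is
configurable; nothing downstream depends on it). The male-vs-female
comparison at a stage is a two-tailed Wilcoxon rank-sum test over the
per-TE abundance vectors, with no multiple-testing correction by
default. Ties and small samples follow the classic policy: exact
enumeration for group sizes ≤ 8 without ties, normal approximation with
tie correction otherwise.

A calibration subtlety: with strongly heterogeneous per-family means the
male and female vectors are paired through the shared family levels, the
pooled sample is not exchangeable, and the rank-sum test becomes
*conservative* (cross-family comparisons are nearly deterministic). Our
type-I calibration therefore runs in the homogeneous-mean regime
(`level_sd = 0` in the generator), where the rank-sum null holds exactly
and the empirical rejection rate sits at the nominal 5%.

**Y-enrichment classification.** A TE family is Y-enriched when its
male/female DNA-seq abundance ratio is ≥ 2. The boundary is inclusive
(a ratio of exactly 2 classifies as Y-enriched) and exposed as a
threshold parameter. Zero female abundance with positive male abundance
gives an infinite ratio, classified Y-enriched and flagged.

# ChIP enrichment and spike-in normalization

Window enrichment at 50-kb resolution is the depth-normalized
ChIP/input ratio:

$$\frac{\text{ChIP reads} / \text{median autosomal coverage (ChIP)}}
       {\text{input reads} / \text{median autosomal coverage (input)}}$$

Reads are counted by midpoint (each read in exactly one window); the
per-library normalizer is the median per-bp coverage over autosomal
contigs, computed by weighted median over the coverage run-length
encoding. Uniform depth rescaling of either library cancels exactly.
Windows with zero input reads are `NA` — missing, never infinite. A
`mapq_min` filter provides the uniquely-mapped-reads variant. Note that
the median-coverage normalizer equals baseline coverage only while most
of the autosome is unenriched; on a genome where a large fraction of
autosomal sequence is enriched the median shifts off baseline and all
windows scale accordingly. Real autosomes satisfy the assumption; test
fixtures should too.

**Spike-in quantile normalization.** Every library contains the same
foreign spike chromatin, so differences between libraries' spike
enrichment distributions measure antibody pulldown efficiency, not
biology. We build a reference by averaging the spike tracks per window
and sorting; each library's spike values are quantile-matched to that
reference (i-th smallest spike value → i-th smallest reference value),
defining a monotone value→value correction map; the map is then applied
to the library's own genome. At observed spike values the transfer is
exact — spike 1.5 corrected to 2 sends sample windows at 1.5 to 2.

Two cases the matching rule does not define were decided as follows.
Sample values *between* observed spike values are corrected by
piecewise-linear interpolation between the sorted (spike, corrected)
pairs — continuous, monotone, and reducing to the exact rule at observed
values; values beyond the spike range get constant extrapolation and are
counted in an `n_extrapolated` attribute. Tied spike values get the mean
of their corrected values, which preserves monotonicity. The map is
idempotent: re-normalizing with an already-matched spike track is the
identity to numerical tolerance.

# Interval analyses

All interval work runs on 0-based half-open coordinates internally (BED
on disk, GFF3 emitted 1-based closed), with IRanges/GenomicRanges doing
overlap and nearest-neighbour queries; every operation is checked in the
test suite against quadratic brute-force oracles.

* Window classes: a window "overlaps a gene" under any-overlap on
  half-open intervals — a 1-bp touch counts. Classes are nested
  (zygotic ⊆ gene ⊆ all) and compared pairwise by two-tailed rank-sum
  tests, skipped with a warning when a class is empty.
* Meta-profiles: per-bp enrichment in ±5000 bp around anchors, median
  across anchors at each relative position. TSS anchors are
  strand-oriented (upstream = the gene's 5′ side); TE midpoint anchors
  are unoriented. Positions beyond a chromosome end contribute missing
  values rather than truncating the profile.
* Gene–TE distances: the edge gap in bp, 0 on any overlap; the
  "internal insertion" fraction counts TEs lying entirely within the
  gene body. Genes on TE-free chromosomes get `NA`.
* Near-gene insertion counts: an insertion qualifies when its interval
  distance to a subset gene is ≤ 5000 bp — the boundary is inclusive,
  so exactly 5000 counts and 5001 does not.
* Family-level regressions are ordinary least squares plus Pearson
  correlation; a constant response reports slope 0 and r = 0.

# The insertion caller

The caller's evidence model: a de novo insertion in some fraction of
cells produces mate pairs with one read in unique flanking sequence and
the mate inside the inserted TE, on both sides of the insertion point.
Four rules turn that into conservative calls:

1. **Junction pairs** — one read maps *uniquely* to the repeat-masked
   genome (mapping quality ≥ 30, single non-secondary record — the
   threshold is a parameter; "uniquely mapped" has no universal
   definition) and its mate maps *only* to the TE consensus library. No
   orientation is imposed on the TE-side mate, since TEs insert in
   either direction.
2. **Clustering** — same-orientation reads of one family within
   < 100 bp capture the same junction. The pairwise rule is ambiguous
   for chains, so chaining is single-linkage (transitive) by default
   with a max-diameter alternative. The representative position is the
   innermost base toward the insertion point: max end for forward
   clusters, min start for reverse — junctions bracket the site.
3. **Dual-junction calls** — a call needs a forward (5′) junction
   followed by a reverse (3′) junction < 100 bp downstream, of the same
   family (cross-family pairing is a flag). Candidate partners are
   paired one-to-one greedily by nearest distance, ties by higher
   support then leftmost; each cluster is used at most once. Chimeric
   library artifacts produce single junctions and are rejected here.
4. **Novelty** — a genuine de novo event is private to one embryo, so
   any call with a call from *another* sample within < 50 bp (same
   chromosome, by 5′ position) is removed from both samples. One mutual
   proximity rule subsumes both "found in more than one sample" and the
   50-bp radius.

The exon control reruns the identical pipeline with exon sequences in
place of the repeat library. Exonic reads also map to the (unmasked)
genic genome, so they fail the "maps only to the library" requirement,
and chimeric mates implicate TEs rather than exons: observed control
calls therefore measure the pipeline's artifact floor.

# Insertion-count models

Library-level insertion counts are modelled by sequential (type-I)
ANOVA, `count ~ coverage + sex + stage`, in that term order — coverage
(the median autosomal per-bp coverage) is the dominant nuisance and is
fitted first; stage enters categorically by default with an ordinal
flag. Collinear designs (sex aliased with stage) are an error. The
library-size effect is alternatively removed by OLS of count on
coverage, with male/female residuals compared per stage by two-tailed
rank-sum tests; a numerically perfect fit reports "no difference"
(p = 1) instead of testing noise.

Chromosomal distribution: under a uniform insertion rate the expected
count on a chromosome is the observed genome-wide total times the
chromosome's share of the sex-specific diploid genome (female: two
copies of each autosome and X, no Y; male: two autosomes, one X, one Y;
copy numbers are configurable for neo-sex karyotypes). Expected counts
are integer-rounded by the largest-remainder method so they always sum
exactly to the observed total. Each chromosome is tested by a 2×2
Fisher's exact test of on/off-chromosome counts, observed vs expected.
That construction treats the (nearly deterministic) expected column as a
second sample, so it is intrinsically conservative — its effective z is
inflated by about √2 and the uniform-rate rejection rate falls well
below nominal. It never over-rejects, which is the property that matters
for the claims built on it; the package also provides a binomial test of
the on-chromosome proportion, which is calibrated at the nominal rate
and is what our type-I simulations exercise.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed and documented here.

* **Genome**: four chromosomes (two autosomes, X, Y) of 0.6–0.8 Mb,
  uniform random sequence; TE library of 20 families, 400–1500 bp
  consensus each; germline copies planted non-overlapping at 30/Mb on
  autosomes vs 120/Mb on the Y (the repeat-dense, still gene-bearing
  neo-Y architecture); genes at 25–60/Mb, 30% flagged zygotic, a
  quarter placed adjacent to TE copies. Densities that cannot be placed
  after bounded retries are an error naming the chromosome.
* **DNA reads**: fragment count `ceiling(depth × G / (2 × read_len))`;
  fragment length normal with mean 500 bp, sd 50 (the real libraries'
  insert-size distribution is not knowable from public summaries, so it
  is configurable; 500 bp gives junction-flank windows of ~300 bp so
  that 30× coverage at cell fraction 1 yields tens of supporting pairs
  per junction). Cell fraction is implemented at the fragment level —
  each fragment overlapping the insertion point is drawn from the
  insertion haplotype with that probability — statistically equivalent
  to per-cell simulation at these scales. Reads fully inside planted
  repeats align only to the TE library (the genome is repeat-masked);
  junction-straddling reads are emitted unaligned, as a real aligner
  would soft-clip them. Chimeric artifacts are generated
  single-junction *by construction*: placements that would coincidentally
  complete a dual junction (two same-family chimeras, or a chimera near
  a planted insertion, within 300 bp) are re-drawn, because the artifact
  class being modelled is the TE-to-unique fusion fragment, which has no
  matching opposite junction.
* **RNA counts**: negative-binomial with stage×sex mean structure —
  sex-independent maternal means before the transition stage (default
  5), a male fold on Y-linked TE families after it. TE features carry a
  50× level factor over genes: family-level TE counts aggregate reads
  over many genomic copies, which also keeps the +1 pseudocount
  negligible for TE fold estimation. The dispersion-zero limit returns
  exact means so that constructed ratios are exact.
* **ChIP reads**: input uniform over sample + spike genomes with a 20%
  spike chromatin share (the fixed-percentage spike design); ChIP reads
  drawn per window proportional to `distortion(true enrichment)`, the
  same monotone distortion applied to sample and spike chromatin — the
  assumption the spike-in correction relies on. The spike truth
  landscape is a fixed, library-independent pattern.

What the generator deliberately does not model: sequencing errors and
quality scores, polymorphism, mappability structure beyond exact
repeat-masking, germline-vs-somatic lineage structure, and GC or
fragment-length biases. Passing tests demonstrate the *logic* of each
stage against known truth at desk scale; they do not certify behaviour
on real libraries with alignment noise and incomplete repeat masking.

# Problem sizes and calibration choices in the test suite

The validation suite runs the caller end-to-end on 1–2.8 Mb genomes at
8–30× (hundreds of thousands of read pairs), fold recovery at 300 TE
families with three replicates per sex, rank-sum and uniform-rate
calibrations at 1000 replicates, and coefficient recovery at 500
simulated designs of 30 libraries — sizes chosen so the whole suite
exercises every code path in well under typical CI budgets while keeping
Monte-Carlo standard errors far inside the asserted tolerances.
Coefficient recovery is asserted per parameter against twice the true
sampling standard error (a ±2·SE normal interval covers 95.45%);
demanding both parameters jointly would have nominal coverage near 91%
and could never meet a 95% bar.

# Known limitations

* The caller uses fragment-orientation evidence only; split-read
  (clipped base) evidence and target-site-duplication signals are out of
  scope, so breakpoints are resolved to ~tens of bp, not base pairs.
* Insertions closer than the novelty radius to a genuine event in
  another sample are removed as shared — with very many samples the
  filter grows conservative.
* The spike-in correction assumes the distortion is monotone and shared
  between spike and sample chromatin; non-monotone or
  compartment-specific distortions are not identifiable from one spike.
* `exon_control` assumes exonic sequence is not repeat-masked; genomes
  masked otherwise would need a matched control index.
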