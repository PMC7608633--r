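#' Classify enrichment windows by gene overlap
#'
#' Splits the windows of a track (optionally restricted to one
#' chromosome, typically the Y) into nested classes — all windows,
#' windows overlapping an annotated gene, and windows overlapping a
#' zygotically expressed gene (any-overlap on half-open intervals) — and
#' compares the class enrichment distributions pairwise with two-tailed
#' Wilcoxon rank-sum tests (no multiple-testing correction).
#'
#' @param track window `enrichment_track`.
#' @param annotation `genome_annotation`.
#' @param chrom optional chromosome name(s) to restrict to.
#' @return list with `class` (per-window factor: "none", "gene",
#'   "zygotic" — nested, a zygotic window is also a gene window),
#'   `values` (list of enrichment vectors for all/gene/zygotic) and
#'   `tests` (data.frame of pairwise p-values; comparisons with an empty
#'   class are skipped with a warning).
#' @export
window_gene_classes <- function(track, annotation, chrom = NULL) {
  w <- track
  if (!is.null(chrom)) w <- w[w$chrom %in% chrom, , drop = FALSE]
  genes <- annotation$genes
  if (!is.null(chrom)) genes <- genes[genes$chrom %in% chrom, ,
                                      drop = FALSE]
  wgr <- GenomicRanges::GRanges(w$chrom,
                                IRanges::IRanges(w$start + 1L, w$end))
  ov_with <- function(g) {
    if (nrow(g) == 0) return(rep(FALSE, length(wgr)))
    ggr <- GenomicRanges::GRanges(g$chrom,
                                  IRanges::IRanges(g$start + 1L, g$end))
    GenomicRanges::countOverlaps(wgr, ggr) > 0L
  }
  has_gene <- ov_with(genes)
  has_zyg <- ov_with(genes[genes$zygotic, , drop = FALSE])
  cls <- ifelse(has_zyg, "zygotic", ifelse(has_gene, "gene", "none"))
  vals <- list(all = w$value,
               gene = w$value[has_gene],
               zygotic = w$value[has_zyg])
  pair <- function(a, b) {
    va <- stats::na.omit(vals[[a]]); vb <- stats::na.omit(vals[[b]])
    if (length(va) == 0 || length(vb) == 0) {
      warning("class ", if (length(va) == 0) a else b,
              " is empty; comparison skipped")
      return(NA_real_)
    }
    stats::wilcox.test(va, vb, alternative = "two.sided", exact = FALSE)$p.value
  }
  tests <- data.frame(
    comparison = c("all_vs_gene", "all_vs_zygotic", "gene_vs_zygotic"),
    p = c(pair("all", "gene"), pair("all", "zygotic"),
          pair("gene", "zygotic")))
  list(class = factor(cls, levels = c("none", "gene", "zygotic")),
       values = vals, tests = tests)
}

#' Median meta-profile around anchors
#'
#' Extracts the per-bp enrichment in a window of `flank` bp on either
#' side of each anchor (a TSS or a TE midpoint) and takes the median
#' across anchors at each relative position. TSS anchors are
#' strand-oriented (upstream is the gene's 5' side: minus-strand slices
#' are reversed); midpoint anchors are unoriented. Positions beyond a
#' chromosome end contribute missing values.
#'
#' @param track a `perbp_track` (see [perbp_enrichment()]).
#' @param anchors data.frame with `chrom`, `pos` (0-based bp) and
#'   optionally `strand` (used when `oriented = TRUE`).
#' @param flank half-width F in bp; the profile covers -F..+F.
#' @param oriented orient slices by anchor strand.
#' @return list of class `meta_profile`: `position` (-F..F), `median`
#'   (per-position median across anchors, NA-aware) and `n_anchors`.
#' @export
metaprofile <- function(track, anchors, flank = 5000L, oriented = TRUE) {
  stopifnot(inherits(track, "perbp_track"), nrow(anchors) > 0)
  width <- 2L * flank + 1L
  slices <- matrix(NA_real_, nrow(anchors), width)
  for (i in seq_len(nrow(anchors))) {
    v <- track[[anchors$chrom[i]]]
    if (is.null(v)) next
    p <- anchors$pos[i]
    idx <- (p - flank):(p + flank) + 1L  # 1-based into the track vector
    ok <- idx >= 1L & idx <= length(v)
    s <- rep(NA_real_, width)
    s[ok] <- v[idx[ok]]
    if (oriented && "strand" %in% names(anchors) &&
        identical(anchors$strand[i], "-")) s <- rev(s)
    slices[i, ] <- s
  }
  list(position = seq(-flank, flank),
       median = apply(slices, 2, stats::median, na.rm = TRUE),
       n_anchors = nrow(anchors)) |>
    structure(class = "meta_profile")
}

#' Per-gene distance to the nearest TE
#'
#' For each gene in the subset, the gap in bp between the closest
#' interval edges of the gene and its nearest TE; 0 when a TE overlaps
#' (lies within) the gene. Also reports the fraction of genes with at
#' least one insertion inside the gene body. Genes on chromosomes without
#' TEs get a missing distance.
#'
#' @param annotation `genome_annotation`.
#' @param genes optional gene subset (data.frame like
#'   `annotation$genes`); defaults to all genes.
#' @return list with `distance` (named by gene id, NA when no TE shares
#'   the chromosome), `internal` (logical, >= 1 TE inside the gene) and
#'   `fraction_internal`.
#' @export
gene_te_distances <- function(annotation, genes = annotation$genes) {
  tes <- annotation$tes
  n <- nrow(genes)
  dist <- rep(NA_real_, n)
  internal <- rep(FALSE, n)
  if (n > 0 && nrow(tes) > 0) {
    ggr <- GenomicRanges::GRanges(genes$chrom,
                                  IRanges::IRanges(genes$start + 1L,
                                                   genes$end))
    tgr <- GenomicRanges::GRanges(tes$chrom,
                                  IRanges::IRanges(tes$start + 1L,
                                                   tes$end))
    hit <- GenomicRanges::distanceToNearest(ggr, tgr)
    dist[S4Vectors::queryHits(hit)] <-
      as.numeric(S4Vectors::mcols(hit)$distance)
    # "internal" means the TE copy lies entirely within the gene body
    win <- GenomicRanges::findOverlaps(tgr, ggr, type = "within")
    internal <- seq_len(n) %in% S4Vectors::subjectHits(win)
  }
  list(distance = stats::setNames(dist, genes$gene_id),
       internal = stats::setNames(internal, genes$gene_id),
       fraction_internal = if (n > 0) mean(internal) else NA_real_)
}

#' Count TE insertions near a gene subset, per family
#'
#' Counts, for each TE family, how many of its insertions lie within
#' `flank` bp of (or inside) a gene of the subset — typically zygotically
#' expressed genes on the Y, where reduced silencing lets TEs stay
#' active. The boundary is inclusive: an interval distance of exactly
#' `flank` qualifies. Each insertion is counted once per family however
#' many subset genes it neighbours.
#'
#' @param annotation `genome_annotation`.
#' @param genes gene subset data.frame; defaults to zygotic genes.
#' @param flank distance threshold in bp.
#' @param chrom optional chromosome restriction for the TE insertions.
#' @return named integer vector: qualifying insertion count per family
#'   (all families present in the restricted annotation appear, possibly
#'   with 0).
#' @export
insertions_near_genes <- function(annotation,
                                  genes =
                                    annotation$genes[annotation$genes$zygotic, ],
                                  flank = 5000L, chrom = NULL) {
  tes <- annotation$tes
  if (!is.null(chrom)) tes <- tes[tes$chrom %in% chrom, , drop = FALSE]
  fams <- sort(unique(tes$family))
  out <- stats::setNames(integer(length(fams)), fams)
  if (nrow(tes) == 0 || nrow(genes) == 0) return(out)
  tgr <- GenomicRanges::GRanges(tes$chrom,
                                IRanges::IRanges(tes$start + 1L, tes$end))
  ggr <- GenomicRanges::GRanges(genes$chrom,
                                IRanges::IRanges(genes$start + 1L,
                                                 genes$end))
  hit <- GenomicRanges::distanceToNearest(tgr, ggr)
  near <- S4Vectors::queryHits(hit)[S4Vectors::mcols(hit)$distance <= flank]
  tt <- table(factor(tes$family[near], levels = fams))
  out[] <- as.integer(tt)
  out
}

#' Regress per-family insertion counts on expression
#'
#' Ordinary least squares of `y` on `x` plus the Pearson correlation and
#' its two-sided p-value, over TE families (typically: insertion counts
#' near zygotic genes vs transcript abundance or log2 sex fold).
#'
#' @param counts named numeric vector (e.g. [insertions_near_genes()]).
#' @param expression named numeric vector over the same families.
#' @return list with `slope`, `intercept`, `r`, `p`, `n` and the `lm`
#'   fit.
#' @export
regress_family_counts_vs_expression <- function(counts, expression) {
  common <- intersect(names(counts), names(expression))
  if (length(common) < 3) stop("need at least 3 families in common")
  x <- expression[common]; y <- counts[common]
  fit <- stats::lm(y ~ x)
  if (stats::sd(y) == 0 || stats::sd(x) == 0) {
    r <- 0; p <- 1
  } else {
    ct <- stats::cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = r, p = p, n = length(common), fit = fit)
}
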