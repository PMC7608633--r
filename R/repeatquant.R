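#' Autosomal-median normalization
#'
#' Divides each library's counts by that library's median count over
#' autosomal genes, then adds a pseudocount to every normalized value.
#' Normalizing by autosomal genes avoids the large contribution of
#' sex-specific expression from the sex chromosomes (especially a
#' gene-rich neo-Y) that a total-count normalizer would absorb. The
#' pseudocount keeps downstream log2 transforms defined; by default it is
#' added to all features (genes and TEs), with a flag to restrict it to
#' genes only.
#'
#' @param tab `count_table` to normalize (genes, TEs, or both).
#' @param genes `count_table` of gene counts over the same samples, used
#'   to compute the per-sample normalizer (pass `tab` itself when it
#'   contains the genes).
#' @param chrom_map named character vector mapping gene feature ids to
#'   chromosome class ("autosome", "X", "Y"), or to chromosome names if
#'   `chrom_class` is supplied.
#' @param chrom_class optional named vector mapping chromosome name to
#'   class.
#' @param pseudocount value added after division (default 1).
#' @param pseudo_genes_only if TRUE, add the pseudocount to gene features
#'   only.
#' @return normalized `count_table` (state
#'   "autosomal-median+pseudocount", or "autosomal-median" when
#'   `pseudocount = 0`).
#' @export
normalize_autosomal_median <- function(tab, genes, chrom_map,
                                       chrom_class = NULL,
                                       pseudocount = 1,
                                       pseudo_genes_only = FALSE) {
  stopifnot(inherits(tab, "count_table"), inherits(genes, "count_table"))
  if (!identical(colnames(tab$counts), colnames(genes$counts)))
    stop("tab and genes must cover the same samples in the same order")
  cls <- chrom_map
  if (!is.null(chrom_class)) cls <- chrom_class[chrom_map]
  names(cls) <- names(chrom_map)
  gid <- rownames(genes$counts)[genes$feature_class == "gene"]
  if (any(!gid %in% names(cls)))
    stop("every gene used for normalization needs a chromosome assignment")
  aut <- gid[cls[gid] == "autosome"]
  if (length(aut) == 0) stop("no autosomal genes to normalize by")

  med <- apply(genes$counts[aut, , drop = FALSE], 2, stats::median)
  zero <- med == 0
  if (any(zero))
    stop("median autosomal gene count is 0 in sample(s): ",
         paste(colnames(tab$counts)[zero], collapse = ", "))
  norm <- sweep(tab$counts, 2, med, "/")
  if (pseudocount != 0) {
    if (pseudo_genes_only) {
      g <- tab$feature_class == "gene"
      norm[g, ] <- norm[g, ] + pseudocount
    } else norm <- norm + pseudocount
  }
  out <- tab
  out$counts <- norm
  advance_state(out, if (pseudocount != 0)
    "autosomal-median+pseudocount" else "autosomal-median")
}

#' Copy-number normalization of TE expression
#'
#' Divides each TE's normalized RNA value by the DNA-seq value of the same
#' TE in sex-matched DNA libraries, removing the contribution of genomic
#' copy number to transcript abundance (males carry extra Y-linked
#' copies). The DNA normalizer per RNA sample is the mean over DNA
#' libraries of the same sex (override with `matcher`).
#'
#' @param rna normalized `count_table` of TE expression.
#' @param dna normalized `count_table` of DNA counts over the same TE ids.
#' @param rna_design,dna_design [sample_sheet()]s for the two tables.
#' @param matcher optional function(rna_sample_row, dna_design) returning
#'   the DNA sample ids to average for that RNA sample.
#' @return `count_table` with state "copy-number". TEs with DNA value 0
#'   become `NA` (undefined, not zero) with a warning.
#' @export
copy_number_normalize <- function(rna, dna, rna_design, dna_design,
                                  matcher = NULL) {
  stopifnot(inherits(rna, "count_table"), inherits(dna, "count_table"))
  common <- intersect(rownames(rna$counts), rownames(dna$counts))
  if (length(common) == 0) stop("rna and dna share no feature ids")
  if (is.null(matcher))
    matcher <- function(s, dd) dd$sample_id[dd$sex == s$sex]
  out <- rna[common, ]
  dmat <- dna$counts[common, , drop = FALSE]
  for (j in seq_len(ncol(out$counts))) {
    sid <- colnames(out$counts)[j]
    s <- rna_design[rna_design$sample_id == sid, , drop = FALSE]
    dn_ids <- matcher(s, dna_design)
    if (length(dn_ids) == 0)
      stop("no matched DNA library for RNA sample ", sid)
    dvals <- rowMeans(dmat[, dn_ids, drop = FALSE])
    res <- out$counts[, j] / dvals
    res[dvals == 0] <- NA_real_
    out$counts[, j] <- res
  }
  if (anyNA(out$counts))
    warning("DNA value 0 for some TE(s); copy-number value undefined (NA)")
  if (out$state == "copy-number")
    stop("table is already copy-number normalized")
  out$state <- "copy-number"
  out
}

#' Per-feature log2 male/female fold difference at a stage
#'
#' For each feature, log2 of the ratio of the mean over male replicates to
#' the mean over female replicates at the given developmental stage,
#' computed on normalized (pseudocounted) values.
#'
#' @param tab normalized `count_table`.
#' @param design [sample_sheet()] covering the table's samples.
#' @param stage developmental stage to compare.
#' @param assay assay to restrict the design to (default "RNA").
#' @return named numeric vector of per-feature log2(male/female).
#' @export
sex_fold_difference <- function(tab, design, stage, assay = "RNA") {
  m <- design_rows(design, sex = "male", stage = stage, assay = assay)
  f <- design_rows(design, sex = "female", stage = stage, assay = assay)
  if (nrow(m) == 0 || nrow(f) == 0)
    stop("need replicates of both sexes at stage ", stage)
  mm <- rowMeans(tab$counts[, m$sample_id, drop = FALSE], na.rm = TRUE)
  fm <- rowMeans(tab$counts[, f$sample_id, drop = FALSE], na.rm = TRUE)
  log2(mm / fm)
}

#' Sample correlation matrix and hierarchical clustering
#'
#' Pearson correlation between samples on log2-transformed values, and
#' agglomerative clustering of samples on distance `1 - r` with the
#' configured linkage. Leaf order is deterministic for a given input.
#'
#' @param tab normalized `count_table` (values must be positive; use the
#'   pseudocounted state).
#' @param linkage hclust agglomeration method (default "complete").
#' @return list with `cor` (samples x samples), `hclust`, and `order`
#'   (leaf order as sample ids).
#' @export
correlation_cluster <- function(tab, linkage = "complete") {
  lv <- log2(tab$counts)
  if (any(!is.finite(lv)))
    stop("log2 transform undefined; normalize with a pseudocount first")
  r <- stats::cor(lv, method = "pearson")
  hc <- stats::hclust(stats::as.dist(1 - r), method = linkage)
  list(cor = r, hclust = hc, order = colnames(tab$counts)[hc$order])
}

#' Male vs female Wilcoxon rank-sum test over per-TE abundances
#'
#' Compares the vector of per-TE mean abundances in males against that in
#' females at one stage with a two-tailed Wilcoxon rank-sum test. No
#' multiple-testing correction is applied by default (one test per stage);
#' a correction method can be requested when the function is reused across
#' many feature sets.
#'
#' @param tab normalized `count_table` (TE rows are used).
#' @param design [sample_sheet()].
#' @param stage developmental stage.
#' @param assay assay label to select libraries.
#' @param features optional subset of feature ids to test.
#' @param exact_max use exact enumeration when both vectors have at most
#'   this many untied values (otherwise normal approximation with tie
#'   correction).
#' @return `htest` object from [stats::wilcox.test()].
#' @export
compare_sexes_wilcoxon <- function(tab, design, stage, assay = "RNA",
                                   features = NULL, exact_max = 8) {
  te <- if (is.null(features))
    rownames(tab$counts)[tab$feature_class == "TE"] else features
  if (length(te) == 0) stop("no TE features to test")
  m <- design_rows(design, sex = "male", stage = stage, assay = assay)
  f <- design_rows(design, sex = "female", stage = stage, assay = assay)
  if (nrow(m) == 0 || nrow(f) == 0)
    stop("need libraries of both sexes at stage ", stage)
  mv <- rowMeans(tab$counts[te, m$sample_id, drop = FALSE])
  fv <- rowMeans(tab$counts[te, f$sample_id, drop = FALSE])
  if (length(mv) < 2)
    stop("degenerate input: need at least two features per group")
  exact <- length(mv) <= exact_max && length(fv) <= exact_max &&
    !anyDuplicated(c(mv, fv))
  stats::wilcox.test(mv, fv, alternative = "two.sided", exact = exact,
                     correct = !exact)
}

#' Classify Y-enriched TE families from sexed DNA-seq
#'
#' A TE family is deemed Y-enriched when its (normalized) DNA-seq
#' abundance in males is at least `threshold` times that in females —
#' male-specific sequence is Y-linked, so a twofold male excess marks
#' families residing predominantly on the Y. Female abundance 0 with
#' positive male abundance yields an infinite ratio, classified
#' Y-enriched and flagged.
#'
#' @param dna normalized `count_table` of DNA counts (TE rows used).
#' @param design [sample_sheet()] of the DNA libraries.
#' @param threshold male/female ratio boundary, inclusive (default 2).
#' @return list with `y_enriched` and `remaining` id vectors, and `ratio`
#'   (named male/female abundance ratios; `Inf` flagged as above).
#' @export
classify_y_enriched <- function(dna, design, threshold = 2) {
  te <- rownames(dna$counts)[dna$feature_class == "TE"]
  m <- design_rows(design, sex = "male")
  f <- design_rows(design, sex = "female")
  if (nrow(m) == 0 || nrow(f) == 0)
    stop("need at least one male and one female DNA library")
  mv <- rowMeans(dna$counts[te, m$sample_id, drop = FALSE])
  fv <- rowMeans(dna$counts[te, f$sample_id, drop = FALSE])
  ratio <- mv / fv
  ratio[fv == 0 & mv == 0] <- NA_real_
  y <- !is.na(ratio) & ratio >= threshold
  list(y_enriched = te[y],
       remaining = te[!y],
       ratio = stats::setNames(ratio, te))
}
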