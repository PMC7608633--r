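#' Simulate stage- and sex-structured RNA-seq counts
#'
#' Emulates the expression structure of sexed single-embryo RNA-seq across
#' the maternal-to-zygotic (MZ) transition: before the transition stage the
#' transcript pool is maternally deposited and sex-independent; from the
#' transition stage onward zygotic transcription takes over and male
#' samples inflate Y-linked TE means by a configurable fold. Counts are
#' drawn from a negative-binomial model with the stated dispersion; the
#' dispersion-zero limit returns the expected means themselves, so
#' constructed ratios are exact.
#'
#' @param features either a `genome_annotation` (features are its genes
#'   plus TE families, with Y linkage derived from copy placement) or a
#'   data.frame with columns `feature_id`, `feature_class` ("gene"/"TE")
#'   and `y_linked` (logical).
#' @param design a [sample_sheet()] of RNA libraries.
#' @param maternal_level mean maternal count level (scales all features).
#' @param te_level_factor multiplier on TE feature means: family-level TE
#'   counts aggregate reads over many genomic copies, so they sit well
#'   above single-gene counts (and above the post-normalization
#'   pseudocount).
#' @param zygotic_stage first stage with widespread zygotic transcription.
#' @param male_y_fold fold inflation of Y-linked TE means in
#'   post-transition males.
#' @param dispersion negative-binomial dispersion (variance
#'   \eqn{\mu + \mu^2 \phi}); 0 gives the deterministic limit.
#' @param level_sd standard deviation (log scale) of the per-feature
#'   expression level spread; 0 makes all features of a class share one
#'   mean — the exchangeable regime in which rank-sum calibration checks
#'   are exact.
#' @param seed RNG seed.
#' @return a raw `count_table` (see [count_table()]); its `"truth"`
#'   attribute records the expected-mean matrix and the Y-linked TE ids.
#' @export
simulate_rna_counts <- function(features, design, maternal_level = 100,
                                te_level_factor = 50,
                                zygotic_stage = 5, male_y_fold = 2,
                                dispersion = 0.1, level_sd = 0.5,
                                seed = 1L) {
  feat <- as_feature_table(features)
  stopifnot(nrow(design) > 0)
  set.seed(seed)
  nf <- nrow(feat)
  size_factor <- exp(stats::rnorm(nf, 0, level_sd))  # per-feature level
  size_factor[feat$feature_class == "TE"] <-
    size_factor[feat$feature_class == "TE"] * te_level_factor

  mu <- matrix(0, nf, nrow(design),
               dimnames = list(feat$feature_id, design$sample_id))
  for (j in seq_len(nrow(design))) {
    m <- maternal_level * size_factor
    if (design$stage[j] >= zygotic_stage) {
      boost <- feat$y_linked & feat$feature_class == "TE" &
        design$sex[j] == "male"
      m[boost] <- m[boost] * male_y_fold
    }
    mu[, j] <- m
  }
  counts <- if (dispersion == 0) mu else {
    k <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = nf, dimnames = dimnames(mu))
    k
  }
  tab <- count_table(counts, feature_class = feat$feature_class,
                     state = "raw")
  attr(tab, "truth") <- list(mu = mu,
                             y_te = feat$feature_id[feat$y_linked &
                                                      feat$feature_class == "TE"])
  tab
}

as_feature_table <- function(features) {
  if (inherits(features, "genome_annotation")) {
    genes <- features$genes
    fam <- unique(features$tes$family)
    # a family is Y-linked if most of its planted copies sit on the Y
    ychr <- features$chrom$name[features$chrom$class == "Y"]
    yfrac <- vapply(fam, function(f) {
      cc <- features$tes$chrom[features$tes$family == f]
      mean(cc %in% ychr)
    }, numeric(1))
    rbind(
      data.frame(feature_id = genes$gene_id, feature_class = "gene",
                 y_linked = genes$chrom %in% ychr,
                 stringsAsFactors = FALSE),
      data.frame(feature_id = fam, feature_class = "TE",
                 y_linked = yfrac > 0.5, stringsAsFactors = FALSE))
  } else {
    stopifnot(is.data.frame(features),
              all(c("feature_id", "feature_class", "y_linked") %in%
                    names(features)))
    features
  }
}

#' Build a bare feature table for count simulation
#'
#' @param n_genes,n_tes numbers of gene and TE features.
#' @param y_te_fraction fraction of TE families flagged Y-linked.
#' @return data.frame accepted by [simulate_rna_counts()].
#' @export
feature_table <- function(n_genes = 100, n_tes = 303,
                          y_te_fraction = 0.25) {
  n_y <- round(y_te_fraction * n_tes)
  data.frame(
    feature_id = c(sprintf("gene%04d", seq_len(n_genes)),
                   sprintf("TE%03d", seq_len(n_tes))),
    feature_class = rep(c("gene", "TE"), c(n_genes, n_tes)),
    y_linked = c(rep(FALSE, n_genes),
                 rep(c(TRUE, FALSE), c(n_y, n_tes - n_y))),
    stringsAsFactors = FALSE)
}

#' Simulate sexed DNA-seq counts reflecting TE copy number
#'
#' Per-family DNA read counts proportional to the diploid copy number of
#' the family in each sex (autosomal and X copies count twice in females;
#' males carry one X and one Y complement), times consensus length.
#' Used to exercise Y-enrichment classification and copy-number
#' normalization with known truth.
#'
#' @param genome a `synth_genome`.
#' @param design a [sample_sheet()] of DNA libraries.
#' @param scale expected reads per bp of diploid feature sequence.
#' @param dispersion negative-binomial dispersion; 0 = deterministic.
#' @param seed RNG seed.
#' @return a raw `count_table` over gene and TE features.
#' @export
simulate_dna_counts <- function(genome, design, scale = 0.05,
                                dispersion = 0.05, seed = 1L) {
  set.seed(seed)
  ann <- genome$annotation
  cls <- stats::setNames(ann$chrom$class, ann$chrom$name)
  copy_mult <- function(chrom_class, sex) {
    if (sex == "female")
      c(autosome = 2, X = 2, Y = 0)[chrom_class]
    else
      c(autosome = 2, X = 1, Y = 1)[chrom_class]
  }
  fam <- names(genome$te_library)
  fam_len <- Biostrings::width(genome$te_library)
  genes <- ann$genes
  nf <- length(fam) + nrow(genes)
  mu <- matrix(0, nf, nrow(design),
               dimnames = list(c(genes$gene_id, fam), design$sample_id))
  for (j in seq_len(nrow(design))) {
    sex <- design$sex[j]
    gmult <- copy_mult(cls[genes$chrom], sex)
    mu[seq_len(nrow(genes)), j] <- scale * (genes$end - genes$start) * gmult
    tmult <- vapply(fam, function(f) {
      rows <- ann$tes$family == f
      sum(copy_mult(cls[ann$tes$chrom[rows]], sex))
    }, numeric(1))
    mu[nrow(genes) + seq_along(fam), j] <- scale * fam_len * tmult
  }
  counts <- if (dispersion == 0) mu else
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
           nrow = nf, dimnames = dimnames(mu))
  tab <- count_table(counts,
                     feature_class = rep(c("gene", "TE"),
                                         c(nrow(genes), length(fam))),
                     state = "raw")
  attr(tab, "truth") <- list(mu = mu)
  tab
}
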