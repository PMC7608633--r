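#' Library insertion records
#'
#' One row per library: sex, developmental stage, median autosomal per-bp
#' coverage, and the number of novel insertion calls.
#'
#' @param sample_id,sex,stage,coverage,count column vectors.
#' @return validated data.frame of class `insertion_records`.
#' @export
insertion_records <- function(sample_id, sex, stage, coverage, count) {
  if (any(coverage <= 0)) stop("coverage must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  df <- data.frame(sample_id = as.character(sample_id), sex = sex,
                   stage = as.numeric(stage),
                   coverage = as.numeric(coverage),
                   count = as.numeric(count), stringsAsFactors = FALSE)
  class(df) <- c("insertion_records", "data.frame")
  df
}

#' Sequential ANOVA of insertion counts
#'
#' Fits the model `count ~ coverage + sex + stage` by sequential (type-I)
#' ANOVA in that term order: coverage (numeric covariate for library
#' depth) first, then sex, then developmental stage (categorical by
#' default; set `stage_ordinal = TRUE` for a numeric trend term).
#'
#' @param records an [insertion_records()] data.frame.
#' @param stage_ordinal treat stage as a numeric covariate instead of a
#'   factor.
#' @return list with `table` (the sequential ANOVA table: Df, Sum Sq, F,
#'   p per term) and `fit` (the underlying `aov`).
#' @export
fit_anova <- function(records, stage_ordinal = FALSE) {
  if (length(unique(records$sex)) < 2)
    stop("need both sexes in the design")
  if (length(unique(records$stage)) < 2)
    stop("need at least two developmental stages")
  d <- records
  d$sex <- factor(d$sex)
  if (!stage_ordinal) d$stage <- factor(d$stage)
  mm <- stats::model.matrix(~ coverage + sex + stage, d)
  if (nrow(d) <= ncol(mm))
    stop("not enough libraries for the model terms")
  if (qr(mm)$rank < ncol(mm))
    stop("collinear design: sex and stage terms are aliased")
  fit <- stats::aov(count ~ coverage + sex + stage, data = d)
  list(table = summary(fit)[[1]], fit = fit)
}

#' Coverage-adjusted residual comparison by sex
#'
#' Regresses insertion counts on median autosomal coverage (OLS with
#' intercept) to remove the library-size effect, then compares the
#' residuals of male vs female libraries within each developmental stage
#' by two-tailed Wilcoxon rank-sum tests (no multiple-testing
#' correction). When the fit is perfect the residuals are all zero and
#' each test degenerates; it is reported as no difference (p = 1).
#'
#' @param records an [insertion_records()] data.frame.
#' @return list with `residuals` (records plus a `residual` column),
#'   `fit` (the `lm`), and `tests` (data.frame: stage, n_female, n_male,
#'   p).
#' @export
coverage_residuals <- function(records) {
  fit <- stats::lm(count ~ coverage, data = records)
  rec <- records
  rec$residual <- stats::residuals(fit)
  stages <- sort(unique(rec$stage))
  tol <- 1e-8 * (stats::sd(records$count) + 1)  # perfect-fit threshold
  tests <- do.call(rbind, lapply(stages, function(st) {
    f <- rec$residual[rec$stage == st & rec$sex == "female"]
    m <- rec$residual[rec$stage == st & rec$sex == "male"]
    p <- if (length(f) == 0 || length(m) == 0) NA_real_
    else if (stats::sd(c(f, m)) <= tol) 1
    else stats::wilcox.test(m, f, alternative = "two.sided",
                            exact = FALSE)$p.value
    data.frame(stage = st, n_female = length(f), n_male = length(m),
               p = p)
  }))
  list(residuals = rec, fit = fit, tests = tests)
}

# largest-remainder rounding: integer vector summing to `total`
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- total - sum(fl)
  if (rem > 0) {
    o <- order(x - fl, decreasing = TRUE)
    fl[o[seq_len(rem)]] <- fl[o[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Chromosomal distribution of insertions vs uniform expectation
#'
#' Under a uniform insertion rate, the expected number of insertions on a
#' chromosome is the genome-wide observed total multiplied by the
#' chromosome's share of the sex-specific diploid genome (female:
#' autosomes and X twice, no Y; male: autosomes twice, X and Y once —
#' configurable via `copies`). Expected counts are rounded by the
#' largest-remainder method so they sum exactly to the observed total.
#' Each chromosome is then tested with a 2x2 Fisher's exact test of
#' on-chromosome vs off-chromosome counts, observed vs expected (a
#' binomial test of the on-chromosome proportion is available as an
#' alternative).
#'
#' @param calls data.frame of insertion calls with a `chrom` column (e.g.
#'   [filter_novel()] output).
#' @param chrom_table chromosome table (`name`, `length`, `class`).
#' @param sex "female" or "male".
#' @param copies optional named vector of diploid copy number per
#'   chromosome class, overriding the sex defaults.
#' @param test "fisher" or "binomial".
#' @return data.frame: chromosome, length, copies, observed, expected,
#'   p-value and enrichment direction.
#' @export
chromosome_distribution_test <- function(calls, chrom_table, sex,
                                         copies = NULL,
                                         test = c("fisher", "binomial")) {
  test <- match.arg(test)
  sex <- match.arg(sex, c("female", "male"))
  if (is.null(copies))
    copies <- if (sex == "female") c(autosome = 2, X = 2, Y = 0)
  else c(autosome = 2, X = 1, Y = 1)
  ct <- chrom_table
  ct$copies <- copies[ct$class]
  ychr <- ct$name[ct$copies == 0]
  if (any(calls$chrom %in% ychr))
    stop("calls on ", paste(intersect(calls$chrom, ychr), collapse = ","),
         " but that chromosome has 0 copies for sex = ", sex)
  obs <- table(factor(calls$chrom, levels = ct$name))
  total <- sum(obs)
  wt <- ct$length * ct$copies
  expf <- total * wt / sum(wt)
  expe <- largest_remainder(expf, total)
  p <- dir <- rep(NA_real_, nrow(ct))
  for (i in seq_len(nrow(ct))) {
    if (ct$copies[i] == 0) next
    o <- as.integer(obs[i]); e <- expe[i]
    p[i] <- if (test == "fisher")
      stats::fisher.test(matrix(c(o, total - o, e, total - e), 2))$p.value
    else stats::binom.test(o, total, expf[i] / total)$p.value
    dir[i] <- sign(o - expf[i])
  }
  data.frame(chrom = ct$name, length = ct$length, copies = ct$copies,
             observed = as.integer(obs), expected = expe,
             expected_raw = expf, p = p, direction = dir,
             stringsAsFactors = FALSE)
}
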