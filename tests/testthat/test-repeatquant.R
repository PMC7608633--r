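mk_tab <- function(m, class = "TE", state = "raw") {
  count_table(m, feature_class = class, state = state)
}

test_that("count_features tallies primary alignments per target", {
  aln <- list(
    s1 = data.frame(qname = sprintf("r%d", 1:7),
                    family = c(rep("ISY-like", 5), "TEB", "TEB"),
                    secondary = c(rep(FALSE, 5), FALSE, TRUE)),
    s2 = data.frame(qname = "r1", family = "TEB", secondary = TRUE))
  tab <- suppressWarnings(
    count_features(aln, c("ISY-like", "TEB", "TEC")))
  expect_equal(unname(tab$counts[, "s1"]), c(5L, 1L, 0L))
  # secondary-only alignments tally nothing
  expect_equal(unname(tab$counts[, "s2"]), c(0L, 0L, 0L))
  expect_warning(count_features(list(s3 = NULL), c("A", "B")), "empty")
})

test_that("autosomal-median normalization follows the stated arithmetic", {
  genes <- mk_tab(matrix(c(10, 20, 30), 3, 1,
                         dimnames = list(c("gA", "gB", "gC"), "s1")),
                  class = "gene")
  te <- mk_tab(matrix(40, 1, 1, dimnames = list("TE1", "s1")))
  cm <- c(gA = "autosome", gB = "autosome", gC = "autosome")
  norm <- normalize_autosomal_median(te, genes, cm)
  expect_equal(unname(norm$counts[1, 1]), 40 / 20 + 1)
  expect_equal(norm$state, "autosomal-median+pseudocount")
  # per-library scale invariance: one library x7 changes nothing
  genes7 <- genes; genes7$counts <- genes7$counts * 7
  te7 <- te; te7$counts <- te7$counts * 7
  expect_equal(normalize_autosomal_median(te7, genes7, cm)$counts,
               norm$counts)
  # zero median is a hard error naming the sample
  genes0 <- mk_tab(matrix(0, 3, 1, dimnames = dimnames(genes$counts)),
                   class = "gene")
  expect_error(normalize_autosomal_median(te, genes0, cm), "s1")
})

test_that("normalization matches a brute-force oracle on a random table", {
  set.seed(91)
  m <- matrix(rpois(24, 50), 6, 4,
              dimnames = list(c(paste0("g", 1:4), "TE1", "TE2"),
                              paste0("s", 1:4)))
  tab <- mk_tab(m, class = rep(c("gene", "TE"), c(4, 2)))
  cm <- c(g1 = "autosome", g2 = "autosome", g3 = "X", g4 = "autosome")
  norm <- normalize_autosomal_median(tab, tab, cm)
  for (j in 1:4) {
    aut <- sort(m[c("g1", "g2", "g4"), j])
    med <- aut[2]  # median of three sorted values
    expect_equal(unname(norm$counts[, j]), unname(m[, j] / med + 1))
  }
  # feature set is conserved, only values change
  expect_identical(rownames(norm$counts), rownames(m))
})

test_that("copy-number normalization divides by matched-sex DNA values", {
  rna_des <- sample_sheet(c("rf", "rm"), sex = c("female", "male"),
                          stage = 5, assay = "RNA")
  dna_des <- sample_sheet(c("df", "dm"), sex = c("female", "male"),
                          stage = 5, assay = "DNA")
  rna <- mk_tab(matrix(c(2, 4), 1, 2, dimnames = list("TE1", c("rf", "rm"))),
                state = "autosomal-median+pseudocount")
  dna <- mk_tab(matrix(c(1, 2), 1, 2, dimnames = list("TE1", c("df", "dm"))),
                state = "autosomal-median+pseudocount")
  cn <- copy_number_normalize(rna, dna, rna_des, dna_des)
  # male/female RNA fold 2 and DNA fold 2 cancel to 1
  expect_equal(unname(cn$counts[1, "rm"] / cn$counts[1, "rf"]), 1)
  expect_equal(cn$state, "copy-number")
  # DNA all 1 leaves the table unchanged
  dna1 <- mk_tab(matrix(1, 1, 2, dimnames = list("TE1", c("df", "dm"))),
                 state = "autosomal-median+pseudocount")
  expect_equal(copy_number_normalize(rna, dna1, rna_des, dna_des)$counts,
               rna$counts)
  # element-wise division oracle on a random table
  set.seed(17)
  R <- matrix(runif(10, 1, 5), 5, 2,
              dimnames = list(paste0("T", 1:5), c("rf", "rm")))
  D <- matrix(runif(10, 1, 3), 5, 2,
              dimnames = list(paste0("T", 1:5), c("df", "dm")))
  cn2 <- copy_number_normalize(
    mk_tab(R, state = "autosomal-median+pseudocount"),
    mk_tab(D, state = "autosomal-median+pseudocount"),
    rna_des, dna_des)
  expect_equal(unname(cn2$counts[, "rf"]), unname(R[, "rf"] / D[, "df"]))
  expect_equal(unname(cn2$counts[, "rm"]), unname(R[, "rm"] / D[, "dm"]))
  # DNA zero becomes missing, not zero
  D0 <- D; D0[1, ] <- 0
  expect_warning(
    cn0 <- copy_number_normalize(
      mk_tab(R, state = "autosomal-median+pseudocount"),
      mk_tab(D0, state = "autosomal-median+pseudocount"),
      rna_des, dna_des), "undefined")
  expect_true(all(is.na(cn0$counts[1, ])))
})

test_that("sex fold differences are log2 ratios of replicate means", {
  des <- sample_sheet(paste0("s", 1:4),
                      sex = c("female", "female", "male", "male"),
                      stage = 5, replicate = c(1, 2, 1, 2), assay = "RNA")
  m <- matrix(c(1, 1, 1, 1,   # equal means -> 0
                1, 1, 4, 4),  # male 4, female 1 -> 2
              2, 4, byrow = TRUE,
              dimnames = list(c("TEa", "TEb"), paste0("s", 1:4)))
  tab <- mk_tab(m, state = "autosomal-median+pseudocount")
  fold <- sex_fold_difference(tab, des, stage = 5)
  expect_equal(unname(fold), c(0, 2))
  expect_error(sex_fold_difference(tab, des, stage = 7), "stage")
})

test_that("correlation clustering is deterministic and separates structure", {
  set.seed(23)
  base <- runif(30, 1, 10)
  m <- cbind(a1 = base, a2 = base * 1.02,
             b1 = 11 - base, b2 = 11.2 - base)
  rownames(m) <- paste0("TE", 1:30)
  tab <- mk_tab(m, state = "autosomal-median+pseudocount")
  cc <- correlation_cluster(tab)
  expect_equal(diag(cc$cor), rep(1, 4), ignore_attr = TRUE)
  grp <- cutree(cc$hclust, k = 2)
  expect_equal(grp[["a1"]], grp[["a2"]])
  expect_equal(grp[["b1"]], grp[["b2"]])
  expect_true(grp[["a1"]] != grp[["b1"]])
  # duplicated columns: perfect correlation, adjacent leaves
  md <- cbind(m, a1dup = m[, "a1"])
  ccd <- correlation_cluster(mk_tab(md,
                                    state = "autosomal-median+pseudocount"))
  expect_equal(ccd$cor["a1", "a1dup"], 1)
  pos <- match(c("a1", "a1dup"), ccd$order)
  expect_equal(abs(diff(pos)), 1)
  # permuting columns preserves the merge structure
  perm <- c(3, 1, 4, 2)
  ccp <- correlation_cluster(mk_tab(m[, perm],
                                    state = "autosomal-median+pseudocount"))
  expect_equal(sort(ccp$hclust$height), sort(cc$hclust$height))
})

test_that("rank-sum p-values match exact enumeration for small groups", {
  des <- sample_sheet(c("f1", "m1"), sex = c("female", "male"),
                      stage = 5, assay = "RNA")
  set.seed(37)
  for (rep in 1:3) {
    mv <- round(runif(6, 10, 20), 3)
    fv <- round(runif(6, 8, 16), 3)
    m <- cbind(f1 = fv, m1 = mv)
    rownames(m) <- paste0("TE", 1:6)
    tab <- mk_tab(m, state = "autosomal-median+pseudocount")
    got <- compare_sexes_wilcoxon(tab, des, stage = 5)
    expect_equal(got$p.value, oracle_wilcox_exact(mv, fv),
                 tolerance = 1e-10)
  }
  # identical vectors: maximal p under the tie policy
  m <- cbind(f1 = 1:6, m1 = 1:6)
  rownames(m) <- paste0("TE", 1:6)
  p <- compare_sexes_wilcoxon(mk_tab(m, state =
                                       "autosomal-median+pseudocount"),
                              des, stage = 5)$p.value
  expect_equal(p, 1)
  # degenerate single-feature input errors
  m1 <- cbind(f1 = 1, m1 = 2)
  rownames(m1) <- "TE1"
  expect_error(compare_sexes_wilcoxon(
    mk_tab(m1, state = "autosomal-median+pseudocount"), des, stage = 5),
    "degenerate")
})

test_that("Y-enrichment classification applies the inclusive twofold rule", {
  des <- sample_sheet(c("df", "dm"), sex = c("female", "male"),
                      stage = 5, assay = "DNA")
  # TE1: 10/4 = 2.5 -> enriched; TE2: 4/10 -> remaining;
  # TE3: 10/5 = 2 exactly -> enriched (inclusive); TE4: 3/0 -> Inf
  m <- matrix(c(4, 10,
                10, 4,
                5, 10,
                0, 3), 4, 2, byrow = TRUE,
              dimnames = list(paste0("TE", 1:4), c("df", "dm")))
  cls <- classify_y_enriched(mk_tab(m, state = "autosomal-median"), des)
  expect_setequal(cls$y_enriched, c("TE1", "TE3", "TE4"))
  expect_setequal(cls$remaining, "TE2")
  expect_equal(unname(cls$ratio["TE4"]), Inf)
  # partition equals a brute-force threshold scan on a 303-feature table
  set.seed(41)
  M <- matrix(runif(606, 0.5, 10), 303, 2,
              dimnames = list(sprintf("T%03d", 1:303), c("df", "dm")))
  scan <- rownames(M)[M[, "dm"] / M[, "df"] >= 2]
  cls2 <- classify_y_enriched(mk_tab(M, state = "autosomal-median"), des)
  expect_setequal(cls2$y_enriched, scan)
  expect_equal(length(cls2$y_enriched) + length(cls2$remaining), 303)
})

test_that("simulated counts survive the whole quantification path scale-invariantly", {
  des <- sample_sheet(sprintf("s%d", 1:4),
                      sex = rep(c("female", "male"), 2),
                      stage = rep(c(2, 5), each = 2), assay = "RNA")
  ft <- feature_table(n_genes = 20, n_tes = 30)
  tab <- simulate_rna_counts(ft, des, seed = 52)
  cm <- stats::setNames(rep("autosome", 20), ft$feature_id[1:20])
  norm <- normalize_autosomal_median(tab, tab, cm)
  scaled <- tab
  scaled$counts[, "s2"] <- scaled$counts[, "s2"] * 13
  norm2 <- normalize_autosomal_median(scaled, scaled, cm)
  expect_equal(norm2$counts, norm$counts)
  f1 <- sex_fold_difference(norm, des, stage = 5)
  f2 <- sex_fold_difference(norm2, des, stage = 5)
  expect_equal(f1, f2)
})
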