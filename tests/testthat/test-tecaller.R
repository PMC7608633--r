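test_that("junction pairs require a unique genome read and a TE-only mate", {
  g <- rbind(
    g_rec("both", 1L, "c1", 1000L, "+"),        # both ends genomic
    g_rec("both", 2L, "c1", 1400L, "-"),
    g_rec("good", 1L, "c1", 2000L, "+"),        # mate TE-only
    g_rec("multi", 1L, "c1", 3000L, "+"),       # genome-side multimaps
    g_rec("multi", 1L, "c1", 9000L, "+", secondary = TRUE),
    g_rec("lowq", 1L, "c1", 4000L, "+", mapq = 5),
    g_rec("teboth", 1L, "c1", 5000L, "+"),      # mate maps genome AND TE
    g_rec("teboth", 2L, "c1", 5400L, "-"))
  t <- rbind(t_rec("good", 2L, "TE01"),
             t_rec("multi", 2L, "TE01"),
             t_rec("lowq", 2L, "TE01"),
             t_rec("teboth", 2L, "TE01"))
  p <- find_junction_pairs(g, t, mapq_min = 30)
  expect_equal(p$qname, "good")
  expect_equal(p$family, "TE01")
  expect_equal(p$pos, 2100L)  # forward read: innermost base is its end
  rv <- find_junction_pairs(g_rec("r", 2L, "c1", 7000L, "-"),
                            t_rec("r", 1L, "TE02"))
  expect_equal(rv$pos, 7000L)  # reverse read: innermost base is its start
})

test_that("junction chaining follows the pairwise <100 bp rule", {
  mk <- function(pos, strand = "+", fam = "TE01", sample = "s1") {
    data.frame(sample_id = sample, qname = paste0("q", seq_along(pos)),
               chrom = "c1", start = pos - 100L, end = pos,
               strand = strand, pos = pos, family = fam,
               stringsAsFactors = FALSE)
  }
  one <- cluster_junctions(mk(c(100L, 150L)))
  expect_equal(nrow(one), 1)
  expect_equal(one$support, 2)
  expect_equal(one$pos, 150L)  # forward representative: max position
  two <- cluster_junctions(mk(c(100L, 250L)))
  expect_equal(nrow(two), 2)
  # chain 100,180,260: one cluster under single linkage, two under the
  # max-diameter alternative
  chain <- cluster_junctions(mk(c(100L, 180L, 260L)))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$support, 3)
  diam <- cluster_junctions(mk(c(100L, 180L, 260L)), method = "diameter")
  expect_equal(nrow(diam), 2)
  # orientation, family and chromosome partition the clustering
  mixed <- rbind(mk(c(100L, 150L)), mk(c(120L), strand = "-"),
                 mk(c(130L), fam = "TE02"))
  expect_equal(nrow(cluster_junctions(mixed)), 3)
})

test_that("chaining matches a transitive-closure oracle on random positions", {
  set.seed(81)
  for (rep in 1:5) {
    pos <- sort(sample.int(5000L, 60))
    pairs <- data.frame(sample_id = "s1", qname = paste0("q", seq_along(pos)),
                        chrom = "c1", start = pos - 100L, end = pos,
                        strand = "+", pos = pos, family = "TE01",
                        stringsAsFactors = FALSE)
    got <- cluster_junctions(pairs, gap = 100)
    cid <- oracle_cluster_positions(pos, 100)
    expect_equal(nrow(got), length(unique(cid)))
    expect_equal(sort(got$support), sort(unname(table(cid))),
                 ignore_attr = TRUE)
  }
})

test_that("calls require both junctions of one family within the gap", {
  cl <- function(ori, pos, fam = "TE01", support = 5L, sample = "s1") {
    data.frame(sample_id = sample, chrom = "c1", orientation = ori,
               family = fam, pos = pos, support = support,
               min_pos = pos, max_pos = pos, stringsAsFactors = FALSE)
  }
  calls <- call_insertions(rbind(cl("forward", 1000L), cl("reverse", 1050L)))
  expect_equal(nrow(calls), 1)
  expect_equal(calls$pos5, 1000L)
  expect_equal(calls$pos3, 1050L)
  # a lone forward junction never calls
  expect_equal(nrow(call_insertions(cl("forward", 1000L))), 0)
  # junctions 150 bp apart violate the <100 bp rule
  expect_equal(nrow(call_insertions(
    rbind(cl("forward", 1000L), cl("reverse", 1150L)))), 0)
  # family agreement is required by default, optional otherwise
  cross <- rbind(cl("forward", 1000L, "TE01"), cl("reverse", 1050L, "TE02"))
  expect_equal(nrow(call_insertions(cross)), 0)
  expect_equal(nrow(call_insertions(cross, same_family = FALSE)), 1)
  # greedy one-to-one: two forwards, one reverse -> single call to the
  # nearest forward
  trio <- rbind(cl("forward", 1000L), cl("forward", 1040L),
                cl("reverse", 1050L))
  got <- call_insertions(trio)
  expect_equal(nrow(got), 1)
  expect_equal(got$pos5, 1040L)
})

test_that("the novelty filter removes shared calls mutually", {
  call_row <- function(sample, pos, chrom = "c1") {
    data.frame(sample_id = sample, chrom = chrom, pos5 = pos,
               pos3 = pos + 20L, family = "TE01", support5 = 3L,
               support3 = 3L, novel = NA, stringsAsFactors = FALSE)
  }
  shared <- rbind(call_row("s1", 5000L), call_row("s2", 5000L),
                  call_row("s1", 9000L))
  out <- filter_novel(shared)
  expect_equal(out$pos5, 9000L)
  expect_true(all(out$novel))
  # 60 bp apart in two samples: both retained
  apart <- rbind(call_row("s1", 5000L), call_row("s2", 5060L))
  expect_equal(nrow(filter_novel(apart)), 2)
  # same-sample neighbours do not trigger removal
  same <- rbind(call_row("s1", 5000L), call_row("s1", 5010L))
  expect_equal(nrow(filter_novel(same)), 2)
  # random multi-sample fixture against the quadratic oracle
  set.seed(82)
  rand <- do.call(rbind, lapply(1:4, function(k)
    do.call(rbind, lapply(sample.int(3000L, 40), function(p)
      call_row(paste0("s", k), p)))))
  expect_equal(filter_novel(rand)$pos5, oracle_novel(rand, 50)$pos5)
})

test_that("the caller is invariant to input record order", {
  set.seed(83)
  c1 <- junction_cloud("s1", "c1", 10000L, "TE01")
  c2 <- junction_cloud("s1", "c1", 30000L, "TE02")
  g <- rbind(c1$genome, c2$genome)
  t <- rbind(c1$te, c2$te)
  base <- call_te_insertions(g, t, sample_id = "s1")
  perm <- sample(nrow(g))
  shuffled <- call_te_insertions(g[perm, ], t[sample(nrow(t)), ],
                                 sample_id = "s1")
  expect_equal(shuffled, base)
  expect_equal(nrow(base), 2)
})

test_that("removing either junction's fragments removes the call", {
  set.seed(84)
  cloud <- junction_cloud("s1", "c1", 10000L, "TE01", n = 4)
  full <- call_te_insertions(cloud$genome, cloud$te, sample_id = "s1")
  expect_equal(nrow(full), 1)
  expect_gte(full$support5, 1)
  expect_gte(full$support3, 1)
  fwd_only <- cloud$genome$strand == "+"
  norev <- call_te_insertions(cloud$genome[fwd_only, ],
                              cloud$te, sample_id = "s1")
  expect_equal(nrow(norev), 0)
  nofwd <- call_te_insertions(cloud$genome[!fwd_only, ],
                              cloud$te, sample_id = "s1")
  expect_equal(nrow(nofwd), 0)
})

test_that("planted insertions are recovered from simulated reads", {
  g <- make_genome(synth_genome_spec(seed = 85))
  g <- plant_insertions(g, n = 6, samples = "s1", cell_fraction = 1,
                        seed = 86)
  rs <- simulate_dna_reads(g, "s1", depth = 30, seed = 87)
  calls <- call_te_insertions(rs)
  truth <- g$truth$insertions
  expect_equal(nrow(calls), 6)
  hits <- vapply(seq_len(nrow(truth)), function(i)
    any(calls$chrom == truth$chrom[i] & calls$family == truth$family[i] &
          abs(calls$pos5 - truth$pos[i]) < 100), logical(1))
  expect_true(all(hits))
  # every truth-labelled junction fragment is recovered; no unlabeled
  # fragment is attributed to a planted family at the insertion site
  pairs <- find_junction_pairs(rs$genome, rs$te, sample_id = "s1")
  lab <- grepl(";ins=", pairs$qname)
  near_truth <- vapply(seq_len(nrow(pairs)), function(k)
    any(truth$chrom == pairs$chrom[k] &
          abs(truth$pos - pairs$pos[k]) < 600), logical(1))
  expect_true(all(near_truth[lab]))
  expect_false(any(near_truth & !lab))
})

test_that("depth never decreases the set of recovered insertions", {
  g <- plant_insertions(make_genome(synth_genome_spec(seed = 88)),
                        n = 4, samples = "s1", cell_fraction = 1,
                        seed = 89)
  recovered <- function(depth) {
    rs <- simulate_dna_reads(g, "s1", depth = depth, seed = 90)
    calls <- call_te_insertions(rs)
    truth <- g$truth$insertions
    truth$ins_id[vapply(seq_len(nrow(truth)), function(i)
      any(calls$chrom == truth$chrom[i] &
            abs(calls$pos5 - truth$pos[i]) < 100), logical(1))]
  }
  lo <- recovered(8)
  hi <- recovered(30)
  expect_true(all(lo %in% hi))
})

test_that("exon control counts the false-positive floor", {
  set.seed(91)
  cloud <- junction_cloud("s1", "c1", 10000L, "TE01", n = 4)
  # clean TE evidence but an empty exon compartment: zero control calls
  ctrl <- exon_control(list(s1 = cloud$genome),
                       list(s1 = t_rec("none", 2L, "exon1")[0, ]))
  expect_equal(unname(ctrl), 0L)
  # single-junction chimeras to exons still produce zero dual-junction
  # calls
  chim_g <- g_rec(paste0("c", 1:20), 1L, "c1",
                  seq(1000L, by = 5000L, length.out = 20), "+")
  chim_t <- t_rec(paste0("c", 1:20), 2L, "exon7")
  ctrl2 <- exon_control(list(s1 = chim_g), list(s1 = chim_t))
  expect_equal(unname(ctrl2), 0L)
  expect_error(exon_control(list(s1 = chim_g), list()), "empty")
})
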