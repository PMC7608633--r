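# Independent brute-force oracles and small fixture builders.
# Oracles deliberately avoid the code paths they check: plain loops and
# all-pairs scans instead of IRanges / vectorized implementations.

tiny_chroms <- function(n = 2, len = 100000L, classes = NULL) {
  data.frame(name = paste0("c", seq_len(n)), length = len,
             class = if (is.null(classes)) "autosome" else classes,
             te_density = 0, gene_density = 0, stringsAsFactors = FALSE)
}

make_annotation <- function(chroms, genes = NULL, tes = NULL) {
  if (is.null(genes))
    genes <- data.frame(chrom = character(), start = integer(),
                        end = integer(), strand = character(),
                        tss = integer(), zygotic = logical(),
                        gene_id = character(), stringsAsFactors = FALSE)
  if (is.null(tes))
    tes <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), stringsAsFactors = FALSE)
  structure(list(chrom = chroms[, c("name", "length", "class")],
                 genes = genes, tes = tes),
            class = "genome_annotation")
}

random_genes <- function(n, chrom, L, width = 500L) {
  start <- sample.int(L - width, n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             strand = strand,
             tss = ifelse(strand == "+", start, start + width - 1L),
             zygotic = sample(c(TRUE, FALSE), n, replace = TRUE),
             gene_id = sprintf("g%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

random_tes <- function(n, chrom, L, width = 300L) {
  start <- sample.int(L - width, n)
  data.frame(chrom = chrom, start = start, end = start + width,
             strand = sample(c("+", "-"), n, replace = TRUE),
             family = sample(sprintf("TE%02d", 1:5), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# interval gap between [s1,e1) and [s2,e2); 0 on overlap
oracle_gap <- function(s1, e1, s2, e2) {
  if (e1 > s2 && e2 > s1) return(0)
  if (s2 >= e1) s2 - e1 else s1 - e2
}

# per-gene nearest-TE distance, all-pairs scan
oracle_gene_te_dist <- function(genes, tes) {
  vapply(seq_len(nrow(genes)), function(i) {
    same <- tes[tes$chrom == genes$chrom[i], , drop = FALSE]
    if (nrow(same) == 0) return(NA_real_)
    min(vapply(seq_len(nrow(same)), function(j)
      oracle_gap(genes$start[i], genes$end[i],
                 same$start[j], same$end[j]), numeric(1)))
  }, numeric(1))
}

# per-family insertion counts within flank of any subset gene
oracle_near_counts <- function(tes, genes, flank) {
  fams <- sort(unique(tes$family))
  out <- stats::setNames(integer(length(fams)), fams)
  for (j in seq_len(nrow(tes))) {
    gs <- genes[genes$chrom == tes$chrom[j], , drop = FALSE]
    if (nrow(gs) == 0) next
    d <- min(vapply(seq_len(nrow(gs)), function(i)
      oracle_gap(tes$start[j], tes$end[j], gs$start[i], gs$end[i]),
      numeric(1)))
    if (d <= flank) out[tes$family[j]] <- out[tes$family[j]] + 1L
  }
  out
}

# exact two-sided rank-sum p-value by enumeration of all group
# assignments (no ties assumed)
oracle_wilcox_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  W_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(length(pooled), n)
  W_all <- apply(combs, 2, function(idx)
    sum(ranks[idx]) - n * (n + 1) / 2)
  mu <- n * length(y) / 2
  mean(abs(W_all - mu) >= abs(W_obs - mu) - 1e-9)
}

# transitive-closure clustering of positions by pairwise < gap rule
oracle_cluster_positions <- function(pos, gap) {
  o <- order(pos)
  p <- pos[o]
  cid <- integer(length(p))
  cur <- 1L
  cid[1] <- 1L
  for (i in seq_along(p)[-1]) {
    if (p[i] - p[i - 1] >= gap) cur <- cur + 1L
    cid[i] <- cur
  }
  cid[order(o)]
}

# quadratic mutual-proximity novelty filter
oracle_novel <- function(calls, radius) {
  keep <- rep(TRUE, nrow(calls))
  for (i in seq_len(nrow(calls))) for (j in seq_len(nrow(calls))) {
    if (i == j) next
    if (calls$chrom[i] == calls$chrom[j] &&
        calls$sample_id[i] != calls$sample_id[j] &&
        abs(calls$pos5[i] - calls$pos5[j]) < radius)
      keep[i] <- FALSE
  }
  calls[keep, , drop = FALSE]
}

# quantile-map oracle: corrected value for each sample entry by
# explicit sorted matching + linear interpolation
oracle_quantile_map <- function(spike, reference, x) {
  o <- order(spike)
  s <- spike[o]; r <- sort(reference)
  vapply(x, function(v) {
    if (v <= s[1]) return(r[1])
    if (v >= s[length(s)]) return(r[length(r)])
    hi <- which(s >= v)[1]
    lo <- hi - 1
    if (s[hi] == s[lo]) return((r[hi] + r[lo]) / 2)
    r[lo] + (r[hi] - r[lo]) * (v - s[lo]) / (s[hi] - s[lo])
  }, numeric(1))
}

# alignment-record builders for caller unit tests
g_rec <- function(qname, mate, chrom, start, strand, mapq = 60,
                  secondary = FALSE, read_len = 100L) {
  data.frame(qname = qname, mate = mate, chrom = chrom, start = start,
             end = start + read_len, strand = strand, mapq = mapq,
             secondary = secondary, stringsAsFactors = FALSE)
}

t_rec <- function(qname, mate, family, secondary = FALSE) {
  data.frame(qname = qname, mate = mate, family = family,
             start = 0L, end = 100L, strand = "+", mapq = 60,
             secondary = secondary, stringsAsFactors = FALSE)
}

# fabricate a junction-pair cloud around an insertion point for cluster
# and call tests: n forward reads ending just below p, n reverse
# starting just above
junction_cloud <- function(sample_id, chrom, p, family, n = 5,
                           spread = 30L, read_len = 100L) {
  fq <- sprintf("%s_f%d_%d", sample_id, p, seq_len(n))
  rq <- sprintf("%s_r%d_%d", sample_id, p, seq_len(n))
  fends <- p - sample.int(spread, n, replace = TRUE) + 1L
  rstarts <- p + sample.int(spread, n, replace = TRUE) - 1L
  g <- rbind(g_rec(fq, 1L, chrom, fends - read_len, "+"),
             g_rec(rq, 1L, chrom, rstarts, "-"))
  t <- rbind(t_rec(fq, 2L, family), t_rec(rq, 2L, family))
  list(genome = g, te = t)
}
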