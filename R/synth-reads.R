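#' Simulate paired-end DNA reads with planted insertion junctions
#'
#' Draws sequencing fragments uniformly over the genome and emits, for each
#' fragment, a forward read at its 5' end and a reverse read at its 3' end,
#' as pre-computed alignment records against (a) the repeat-masked genome
#' and (b) the TE consensus library — the two single-end mapping
#' compartments the insertion caller consumes. Fragments overlapping a
#' de novo insertion carried by this sample are re-drawn from the insertion
#' haplotype with probability equal to the insertion's cell fraction, so
#' junction-spanning mate pairs (one read in unique flank, one in TE
#' sequence) arise on both the 5' and 3' sides of the insertion. A
#' configurable fraction of fragments are chimeric library artifacts:
#' a single TE-to-unique junction with no matching opposite junction.
#'
#' Reads fully inside a germline TE copy align to the consensus library
#' only (the genome is repeat-masked); reads partially overlapping a copy
#' or an insertion junction are emitted as unaligned — a real aligner would
#' soft-clip them, and junction evidence comes from fully contained reads.
#' Read names encode ground-truth labels (`;ins=` / `;chimera`) for
#' verification; the caller never reads them.
#'
#' @param genome a `synth_genome` (see [make_genome()], [plant_insertions()]).
#' @param sample_id library id; selects which planted insertions are carried.
#' @param depth fold coverage (> 0).
#' @param read_len read length in bp.
#' @param insert_mean,insert_sd fragment-length distribution (bp);
#'   `insert_mean` must be at least `2 * read_len`.
#' @param chimera_rate per-fragment probability of a chimeric artifact.
#' @param seed RNG seed.
#' @return object of class `read_set`: list with `genome` and `te`
#'   alignment data.frames (columns `qname`, `mate`, `chrom`/`family`,
#'   `start`, `end` (0-based half-open), `strand`, `mapq`, `secondary`),
#'   an `unaligned` data.frame, and `n_pairs`.
#' @export
simulate_dna_reads <- function(genome, sample_id, depth,
                               read_len = 100L, insert_mean = 500,
                               insert_sd = 50, chimera_rate = 0,
                               seed = 1L) {
  stopifnot(inherits(genome, "synth_genome"))
  if (depth <= 0) stop("depth must be > 0")
  if (insert_mean < 2 * read_len)
    stop("insert size must be at least 2 * read_len")
  set.seed(seed)
  chroms <- genome$annotation$chrom
  G <- sum(chroms$length)
  n_pairs <- ceiling(depth * G / (2 * read_len))

  ci <- sample.int(nrow(chroms), n_pairs, replace = TRUE,
                   prob = chroms$length)
  L <- chroms$length[ci]
  flen <- pmax(2L * read_len,
               as.integer(round(stats::rnorm(n_pairs, insert_mean,
                                             insert_sd))))
  flen <- pmin(flen, L)
  s <- as.integer(floor(stats::runif(n_pairs, 0, L - flen + 1)))
  chrom <- chroms$name[ci]

  chim <- if (chimera_rate > 0)
    stats::runif(n_pairs) < chimera_rate else rep(FALSE, n_pairs)

  # divert fragments overlapping a carried insertion point
  ins <- genome$truth$insertions
  ins <- ins[ins$sample_id == sample_id, , drop = FALSE]
  fam_len <- Biostrings::width(genome$te_library)
  names(fam_len) <- names(genome$te_library)
  diverted_idx <- integer(0); diverted_ins <- integer(0)
  extra <- NULL
  if (nrow(ins) > 0) {
    ins$te_len <- fam_len[ins$family]
    for (k in seq_len(nrow(ins))) {
      ov <- which(!chim & chrom == ins$chrom[k] &
                    s < ins$pos[k] & s + flen > ins$pos[k])
      take <- ov[stats::runif(length(ov)) < ins$cell_fraction[k]]
      diverted_idx <- c(diverted_idx, take)
      diverted_ins <- c(diverted_ins, rep(k, length(take)))
      # top up so haplotype coverage over the inserted TE stays ~uniform
      n_extra <- stats::rpois(1, n_pairs / G * ins$cell_fraction[k] *
                                ins$te_len[k])
      if (n_extra > 0) {
        eflen <- pmax(2L * read_len,
                      as.integer(round(stats::rnorm(n_extra, insert_mean,
                                                    insert_sd))))
        extra <- rbind(extra, data.frame(ins = k, flen = eflen))
      }
    }
  }

  # haplotype start for diverted + extra fragments: uniform over all
  # haplotype fragments overlapping the inserted TE [pos, pos + te_len)
  div <- data.frame(idx = diverted_idx, ins = diverted_ins)
  if (!is.null(extra)) {
    div <- rbind(div,
                 data.frame(idx = NA_integer_, ins = extra$ins))
    dflen <- c(flen[diverted_idx], extra$flen)
  } else dflen <- flen[diverted_idx]
  if (nrow(div) > 0) {
    dpos <- ins$pos[div$ins]; dlen <- ins$te_len[div$ins]
    h <- as.integer(floor(stats::runif(nrow(div), dpos - dflen + 1,
                                       dpos + dlen)))
    div$h <- h; div$flen <- dflen
    div$chrom <- ins$chrom[div$ins]
  }

  # ---- assemble read-level tables ------------------------------------
  keep <- !chim
  keep[diverted_idx] <- FALSE
  gi <- which(keep)
  base_names <- sprintf("%s_frag%07d", sample_id, seq_len(n_pairs))

  reads <- data.frame(
    qname = rep(base_names[gi], 2L),
    mate = rep(c(1L, 2L), each = length(gi)),
    chrom = rep(chrom[gi], 2L),
    a = c(s[gi], s[gi] + flen[gi] - read_len),
    strand = rep(c("+", "-"), each = length(gi)),
    stringsAsFactors = FALSE)
  reads$b <- reads$a + read_len

  out <- classify_reads(reads, genome$annotation$tes)

  # diverted / extra fragments: map haplotype coordinates back
  if (nrow(div) > 0) {
    n_new <- sum(is.na(div$idx))
    dnames <- character(nrow(div))
    dnames[!is.na(div$idx)] <- base_names[div$idx[!is.na(div$idx)]]
    dnames[is.na(div$idx)] <-
      sprintf("%s_xfrag%05d", sample_id, seq_len(n_new))
    dnames <- paste0(dnames, ";ins=", ins$ins_id[div$ins])
    dr <- data.frame(
      qname = rep(dnames, 2L),
      mate = rep(c(1L, 2L), each = nrow(div)),
      chrom = rep(div$chrom, 2L),
      a = c(div$h, div$h + div$flen - read_len),
      strand = rep(c("+", "-"), each = nrow(div)),
      ipos = rep(ins$pos[div$ins], 2L),
      ilen = rep(ins$te_len[div$ins], 2L),
      ifam = rep(ins$family[div$ins], 2L),
      stringsAsFactors = FALSE)
    dr$b <- dr$a + read_len
    dout <- classify_hap_reads(dr, genome$annotation$tes)
    out$genome <- rbind(out$genome, dout$genome)
    out$te <- rbind(out$te, dout$te)
    out$unaligned <- rbind(out$unaligned, dout$unaligned)
  }

  # chimeric fragments: genomic read + TE mate, single junction only.
  # the artifact class is single-junction by construction: placements
  # that would coincidentally complete a dual junction (same family,
  # nearby, or near a planted insertion point) are re-drawn.
  nch <- sum(chim)
  if (nch > 0) {
    cpos <- sample_clear_positions(nch, chroms, genome$annotation$tes,
                                   read_len)
    cname <- paste0(base_names[which(chim)], ";chimera")
    fams <- sample(names(genome$te_library), nch, replace = TRUE)
    cpos <- isolate_chimeras(cpos, fams, genome, chroms, read_len)
    toff <- as.integer(floor(stats::runif(nch) *
                               pmax(1L, fam_len[fams] - read_len + 1L)))
    out$genome <- rbind(out$genome, data.frame(
      qname = cname, mate = 1L, chrom = cpos$chrom, start = cpos$start,
      end = cpos$start + read_len,
      strand = sample(c("+", "-"), nch, replace = TRUE),
      mapq = 60L, secondary = FALSE, stringsAsFactors = FALSE))
    out$te <- rbind(out$te, data.frame(
      qname = cname, mate = 2L, family = fams, start = toff,
      end = toff + pmin(read_len, fam_len[fams]), strand = "+",
      mapq = 60L, secondary = FALSE, stringsAsFactors = FALSE))
  }

  rownames(out$genome) <- rownames(out$te) <- rownames(out$unaligned) <- NULL
  structure(list(genome = out$genome, te = out$te,
                 unaligned = out$unaligned,
                 n_pairs = n_pairs, sample_id = sample_id,
                 read_len = as.integer(read_len)),
            class = "read_set")
}

# classify plain genomic reads against the repeat mask:
# fully inside a TE copy -> TE-library alignment; partial overlap ->
# unaligned; otherwise unique genome alignment
classify_reads <- function(reads, te_copies) {
  if (nrow(reads) == 0) return(empty_read_tables())
  rgr <- GenomicRanges::GRanges(reads$chrom,
                                IRanges::IRanges(reads$a + 1L, reads$b))
  tgr <- GenomicRanges::GRanges(te_copies$chrom,
                                IRanges::IRanges(te_copies$start + 1L,
                                                 te_copies$end))
  any_hit <- GenomicRanges::countOverlaps(rgr, tgr) > 0L
  within <- GenomicRanges::findOverlaps(rgr, tgr, type = "within",
                                        select = "first")
  is_te <- !is.na(within)
  is_split <- any_hit & !is_te
  is_gen <- !any_hit

  gen <- reads[is_gen, , drop = FALSE]
  genome_df <- data.frame(qname = gen$qname, mate = gen$mate,
                          chrom = gen$chrom, start = gen$a, end = gen$b,
                          strand = gen$strand,
                          mapq = rep(60L, nrow(gen)),
                          secondary = rep(FALSE, nrow(gen)),
                          stringsAsFactors = FALSE)
  te <- reads[is_te, , drop = FALSE]
  cp <- within[is_te]
  te_df <- data.frame(qname = te$qname, mate = te$mate,
                      family = te_copies$family[cp],
                      start = te$a - te_copies$start[cp],
                      end = te$b - te_copies$start[cp],
                      strand = te$strand, mapq = rep(60L, nrow(te)),
                      secondary = rep(FALSE, nrow(te)),
                      stringsAsFactors = FALSE)
  un <- reads[is_split, , drop = FALSE]
  un_df <- data.frame(qname = un$qname, mate = un$mate,
                      stringsAsFactors = FALSE)
  list(genome = genome_df, te = te_df, unaligned = un_df)
}

# classify haplotype-coordinate reads around one insertion per row:
# TE occupies [ipos, ipos + ilen) in haplotype coordinates
classify_hap_reads <- function(dr, te_copies) {
  in_left <- dr$b <= dr$ipos
  in_te <- dr$a >= dr$ipos & dr$b <= dr$ipos + dr$ilen
  in_right <- dr$a >= dr$ipos + dr$ilen
  split <- !(in_left | in_te | in_right)

  gen <- dr[in_left | in_right, , drop = FALSE]
  gen$a <- ifelse(gen$a >= gen$ipos + gen$ilen, gen$a - gen$ilen, gen$a)
  gen$b <- gen$a + (dr$b - dr$a)[1L]
  # flank reads can still touch a germline copy; apply the repeat mask
  res <- classify_reads(gen[, c("qname", "mate", "chrom", "a", "b",
                                "strand")], te_copies)
  te <- dr[in_te, , drop = FALSE]
  te_df <- data.frame(qname = te$qname, mate = te$mate,
                      family = te$ifam, start = te$a - te$ipos,
                      end = te$b - te$ipos, strand = te$strand,
                      mapq = rep(60L, nrow(te)),
                      secondary = rep(FALSE, nrow(te)),
                      stringsAsFactors = FALSE)
  un <- dr[split, , drop = FALSE]
  un_df <- rbind(res$unaligned,
                 data.frame(qname = un$qname, mate = un$mate,
                            stringsAsFactors = FALSE))
  list(genome = res$genome, te = rbind(res$te, te_df), unaligned = un_df)
}

empty_read_tables <- function() {
  list(genome = data.frame(qname = character(), mate = integer(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           mapq = integer(), secondary = logical(),
                           stringsAsFactors = FALSE),
       te = data.frame(qname = character(), mate = integer(),
                       family = character(), start = integer(),
                       end = integer(), strand = character(),
                       mapq = integer(), secondary = logical(),
                       stringsAsFactors = FALSE),
       unaligned = data.frame(qname = character(), mate = integer(),
                              stringsAsFactors = FALSE))
}

# re-draw chimera placements that could complete a dual junction:
# no two same-family chimeras within `margin` bp, and none within
# `margin` bp of a planted insertion point
isolate_chimeras <- function(cpos, fams, genome, chroms, read_len,
                             margin = 300L) {
  ins <- genome$truth$insertions
  for (iter in 1:50) {
    bad <- logical(nrow(cpos))
    key <- paste(cpos$chrom, fams)
    for (k in unique(key[duplicated(key)])) {
      idx <- which(key == k)
      p <- cpos$start[idx]
      o <- order(p)
      close <- abs(diff(p[o])) < margin
      hit <- unique(c(o[which(close)], o[which(close) + 1L]))
      bad[idx[hit]] <- TRUE
    }
    if (nrow(ins) > 0) {
      for (i in seq_len(nrow(ins)))
        bad <- bad | (cpos$chrom == ins$chrom[i] &
                        abs(cpos$start - ins$pos[i]) < margin)
    }
    if (!any(bad)) break
    repl <- sample_clear_positions(sum(bad), chroms,
                                   genome$annotation$tes, read_len)
    cpos[bad, ] <- repl
  }
  cpos
}

# n random read-sized positions in unique (non-TE) sequence
sample_clear_positions <- function(n, chroms, te_copies, read_len) {
  got <- NULL
  tgr <- GenomicRanges::GRanges(te_copies$chrom,
                                IRanges::IRanges(te_copies$start + 1L,
                                                 te_copies$end))
  while (is.null(got) || nrow(got) < n) {
    m <- 2L * n
    ci <- sample.int(nrow(chroms), m, replace = TRUE, prob = chroms$length)
    st <- as.integer(floor(stats::runif(m, 0,
                                        chroms$length[ci] - read_len)))
    cand <- data.frame(chrom = chroms$name[ci], start = st,
                       stringsAsFactors = FALSE)
    cgr <- GenomicRanges::GRanges(cand$chrom,
                                  IRanges::IRanges(st + 1L, st + read_len))
    ok <- GenomicRanges::countOverlaps(cgr, tgr) == 0L
    got <- rbind(got, cand[ok, , drop = FALSE])
  }
  got[seq_len(n), , drop = FALSE]
}

#' @export
print.read_set <- function(x, ...) {
  cat("Read set for", x$sample_id, ":", x$n_pairs, "pairs;",
      nrow(x$genome), "genome-aligned,", nrow(x$te), "TE-aligned,",
      nrow(x$unaligned), "unaligned reads\n")
  invisible(x)
}
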